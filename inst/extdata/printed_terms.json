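{
  "comment": "Published series terms of the three worked Keller-Segel examples, transcribed as R-parseable expression strings in the symbols x, t, a, b, c, d, m, n. status 'consistent' = the as-printed recursion reproduces the term symbolically; 'discrepant' = the publication's term differs from its own recursion (see note).",
  "fixtures": [
    {"example_id": "ex1", "field": "u", "order": 1, "status": "consistent",
     "expression": "2*a*exp(-x^2)*m*t*(-1 + 2*x^2)"},
    {"example_id": "ex1", "field": "rho", "order": 1, "status": "consistent",
     "expression": "exp(-x^2)*t*(c*m - n*(d + b*(2 - 4*x^2)))"},
    {"example_id": "ex1", "field": "u", "order": 2, "status": "consistent",
     "expression": "2*a^2*exp(-x^2)*m*t^2*(3 - 12*x^2 + 4*x^4)"},
    {"example_id": "ex1", "field": "rho", "order": 2, "status": "consistent",
     "expression": "1/2*exp(-x^2)*t^2*(d*(-c*m + n*d) + 2*a*c*m*(-1 + 2*x^2) + 2*b*(c*m - 2*d*n)*(-1 + 2*x^2) + 4*b^2*n*(3 - 12*x^2 + 4*x^4))"},
    {"example_id": "ex1", "field": "u", "order": 3, "status": "consistent",
     "expression": "4/3*a^3*exp(-x^2)*m*t^3*(-15 + 90*x^2 - 60*x^4 + 8*x^6)"},
    {"example_id": "ex1", "field": "rho", "order": 3, "status": "consistent",
     "expression": "1/6*exp(-x^2)*t^3*(d^2*(c*m - d*n) + 2*b*d*(-2*c*m + 3*d*n)*(-1 + 2*x^2) + 4*a^2*c*m*(3 - 12*x^2 + 4*x^4) + 4*b^2*(c*m - 3*d*n)*(3 - 12*x^2 + 4*x^4) + 8*b^3*n*(-15 + 90*x^2 - 60*x^4 + 8*x^6) + 2*a*c*m*(d - 2*d*x^2 + b*(6 - 24*x^2 + 8*x^4)))"},

    {"example_id": "ex2_case1", "field": "u", "order": 1, "status": "consistent",
     "expression": "a*exp(-x)*m*t"},
    {"example_id": "ex2_case1", "field": "rho", "order": 1, "status": "consistent",
     "expression": "exp(-x)*(c*m + (b - d)*n)*t"},
    {"example_id": "ex2_case1", "field": "u", "order": 2, "status": "consistent",
     "expression": "1/2*a^2*exp(-x)*m*t^2"},
    {"example_id": "ex2_case1", "field": "rho", "order": 2, "status": "consistent",
     "expression": "1/2*exp(-x)*(a*c*m + (b - d)*(c*m + (b - d)*n))*t^2"},
    {"example_id": "ex2_case1", "field": "u", "order": 3, "status": "consistent",
     "expression": "1/6*exp(-x)*m*(a*t)^3"},
    {"example_id": "ex2_case1", "field": "rho", "order": 3, "status": "consistent",
     "expression": "1/6*exp(-x)*t^3*(a^2*c*m + a*c*(b - d)*m + (b - d)^2*(c*m + (b - d)*n))"},
    {"example_id": "ex2_case1", "field": "u", "order": 4, "status": "consistent",
     "expression": "1/24*exp(-x)*m*(a*t)^4"},
    {"example_id": "ex2_case1", "field": "rho", "order": 4, "status": "consistent",
     "expression": "1/24*exp(-x)*t^4*(a^3*c*m + a^2*c*(b - d)*m + a*c*(b - d)^2*m + (b - d)^3*(c*m + (b - d)*n))"},

    {"example_id": "ex2_case2", "field": "u", "order": 1, "status": "consistent",
     "expression": "2*exp(-2*x^2)*m*t*(-n + a*exp(x^2)*(-1 + 2*x^2))"},
    {"example_id": "ex2_case2", "field": "rho", "order": 1, "status": "consistent",
     "expression": "exp(-x^2)*t*(c*m - n*(d + b*(2 - 4*x^2)))"},
    {"example_id": "ex2_case2", "field": "u", "order": 2, "status": "consistent",
     "expression": "exp(-3*x^2)*m*t^2*(-c*exp(x^2)*m - 6*a*exp(x^2)*n*(-1 + 2*x^2) + 2*a^2*exp(2*x^2)*(3 - 12*x^2 + 4*x^4) + n*(d*exp(x^2) + 2*n + 4*n*x^2 - 6*b*exp(x^2)*(-1 + 2*x^2)))"},
    {"example_id": "ex2_case2", "field": "rho", "order": 2, "status": "consistent",
     "expression": "1/2*exp(-2*x^2)*t^2*(-c*d*exp(x^2)*m + d^2*exp(x^2)*n - 2*c*m*n + 2*a*c*exp(x^2)*m*(-1 + 2*x^2) + 2*b*exp(x^2)*(c*m - 2*d*n)*(-1 + 2*x^2) + 4*b^2*exp(x^2)*n*(3 - 12*x^2 + 4*x^4))"},

    {"example_id": "ex3", "field": "u", "order": 1, "status": "discrepant",
     "expression": "-m*t*(a + 2*n^2*cos(x)^2)*sin(x)",
     "note": "The published u1 carries cos(x)^2 where the example's own order-1 integrand yields sin(x)^2; the difference is 2*m*n^2*t*sin(x)*cos(2*x)."},
    {"example_id": "ex3", "field": "rho", "order": 1, "status": "consistent",
     "expression": "t*sin(x)*(c*m - (b + d)*n)"},
    {"example_id": "ex3", "field": "u", "order": 2, "status": "discrepant",
     "expression": "-m*t*sin(x)*(a + n*t*(2*c*m - a*n - 2*b*n - 2*d*n + n^3 + n^3*cos(2*x))*sin(x)^2)",
     "note": "Inconsistent with the recursion (it even contains an order-t monomial, though every order-2 term must vanish like t^2); follows from the discrepant published u1."},
    {"example_id": "ex3", "field": "rho", "order": 2, "status": "discrepant",
     "expression": "-1/2*t^2*(a*c*m + b*c*m + c*d*m - b^2*n - 2*d*b*n - d^2*n + c*n*m^2 + c*m*n^2*cos(2*x))*sin(x)",
     "note": "Matches the rho-recursion seeded with the published u1 except for the single monomial printed 'cnm2': the derivation yields c*m*n^2 (the reading under which the term is exact); the verbatim c*n*m^2 reading differs by 1/2*c*m*n*(m - n)*t^2*sin(x)."}
  ]
}
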
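Package: ocdheal
Title: Mechanoregulated Finite-Element Simulation of Osteochondral Defect Healing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled finite-element / mechanoregulation simulator of osteochondral
    defect healing in an axisymmetric model of the knee femoral condyle. Each
    simulated day an axisymmetric poroelastic (Biot) boundary-value problem is
    solved for octahedral shear strain and fluid velocity in the defect, the
    biophysical stimulus S = gamma/a + v/b selects the mechanics-favoured tissue
    fate per lattice element, and a 40 x 40 cell-population model (mesenchymal
    stromal cell diffusion, differentiation, mitosis, apoptosis, resorption)
    deposits tissue whose rule-of-mixtures properties feed the next mechanical
    solve. Scaffold implantation (vertical-ring and grid architectures, uniform
    or biphasic strut moduli, porous strut capacity) can be screened for its
    effect on the healing outcome, including standalone axial stiffness of a
    scaffold architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    xml2
Config/testthat/edition: 3
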
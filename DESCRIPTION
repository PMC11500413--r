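Package: pbkop
Title: Generic Physiologically Based Kinetic Modelling of Organophosphate
    Pesticides
Version: 0.1.0
Authors@R:
    person("pbkop", "maintainers", email = "pbkop@example.org",
           role = c("aut", "cre"))
Description: A generic physiologically based kinetic (PBK) simulator for
    organophosphate (OP) pesticides and their metabolites in rat and human.
    Couples a compartmentalized stomach/small-intestine/colon absorption
    model to perfusion-limited parent (organothiophosphate), oxon and
    urinary-metabolite submodels linked by Michaelis-Menten metabolism
    (CYP450 oxidative desulfuration and cleavage, hepatic and plasma PON1
    hydrolysis) and passive renal excretion. Compound-specific parameters
    are predicted by QSPRs (fraction unbound in plasma, blood:plasma ratio,
    tissue:plasma partition coefficients) or fitted from in vitro
    incubation data; conjugated metabolite forms are lumped by weighted
    averaging. Includes toxicokinetic metrics (Cmax, Tmax, AUC),
    predicted-versus-observed fold-difference evaluation, local sensitivity
    analysis on peak free oxon blood concentration, a compiled adaptive
    Runge-Kutta solver that conserves molar mass to round-off, and a
    command-line interface with self-contained fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
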
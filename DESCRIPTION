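Package: lvdyn
Title: Low-Order Dynamic Model of the Left Ventricle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates full cardiac cycles of the left ventricle with a
    three-degree-of-freedom continuum-mechanics model. The ventricular wall
    is a truncated thick-walled prolate spheroid deforming through a family
    of volume-preserving mappings (lengthening, contraction, torsion), with
    helical muscle fibers, Fung-type transversely isotropic passive
    elasticity, Kelvin-Voigt matrix viscosity, and an active fiber stress
    with length-tension, force-velocity and Frank-Starling dependence.
    Weak-form equilibrium reduces the mechanics to three generalized
    equations coupled to a lumped-parameter pulmonary-atrial-aortic-systemic
    circulation with sigmoidal valve resistances, and the resulting
    differential-algebraic system is integrated with an adaptive
    second-order Runge-Kutta scheme in seconds per cycle. Includes static
    passive-inflation solves, per-cycle work accounting, matched-volume
    shape experiments and parameter sensitivity sweeps.
License: MIT
Encoding: UTF-8
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
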
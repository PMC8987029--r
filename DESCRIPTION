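Package: bpyswitch
Title: Design and Kinetic Analysis of Metal-Responsive Enzyme Switches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-based selection of residue pairs for metal-chelating
    linker-group (bipyridinylalanine) incorporation into conformationally
    switchable enzymes, and downstream analysis of high-throughput
    plate-reader screens: C-beta distance filtering between open and closed
    conformational states, Shrake-Rupley solvent accessibility, sliding-window
    initial-rate extraction, dose-response and reversibility classification,
    Michaelis-Menten and substrate-inhibition fitting, and on/off switching
    dynamic-range analysis. Includes synthetic generators for hinge-motion
    toy structures and simulated screening plates used throughout the test
    suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
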
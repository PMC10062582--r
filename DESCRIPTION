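Package: ribomethscore
Title: Detection of 2'-O-Methyl Ribose Modifications in Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens an atomic model against a cryo-EM density map for
    2'-O-methyl ribose modifications. Every candidate residue is
    hypothetically methylated at the 2'-hydroxyl by internal-coordinate
    construction with clash-avoiding torsion selection and optional
    density-guided torsion refinement; the map is probed by trilinear
    interpolation at the methyl carbon position (Sc_MapVal) and at a
    probe displaced along the O2'-methyl bond extended to 2.4 Angstrom,
    whose ratio (Sc_FallOff) separates genuine methyl density from flat
    or adjacent density. Includes MRC2014/CCP4 map and PDB/mmCIF model
    input and output, a synthetic model and map generator with known
    ground truth for validation, top-N recovery statistics, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
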
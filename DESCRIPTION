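Package: vecforce
Title: Vector Contact Forces at the Human-Mattress Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes vector (normal plus shear) contact forces at the
    human-mattress interface by registering a 24x48 pressure-mat grid to a
    3D scan of the deformed mattress surface. Provides pressure-mat I/O and
    windowed averaging, PLY point-cloud I/O, rigid ICP registration with a
    deterministic coarse initializer, per-cell surface-normal estimation,
    scalar-to-vector force decomposition, force-balance validation against
    body weight, reduction of regional force fields to resultant wrenches
    (force, couple, application point) for musculoskeletal model boundary
    conditions, surface-EMG envelope processing to percent-MVC, and a
    synthetic scenario generator with analytic ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RANN,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
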
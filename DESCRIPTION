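Package: mpaconnect
Title: Biophysical Larval Dispersal and Connectivity of Marine Protected Area Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates passive (and diel vertically migrating) larval transport in
    gridded ocean-current fields with a Lagrangian tracker (trilinear velocity
    interpolation, explicit Euler advection, Monin-Ozmidov random-walk horizontal
    diffusion, coastal standstill and open-boundary loss rules), converts final
    larval positions into an MPA-to-MPA connectivity matrix and recruitment
    statistics (connectance, local retention, self-recruitment), analyses the
    directed MPA graph (neighborhoods, strongly and weakly connected clusters,
    betweenness centrality), maps larval export onto the continental shelf, and
    runs sensitivity analyses over pelagic larval duration, vertical migration
    and spawning month. Includes synthetic generators for divergence-free current
    fields, coastlines, bathymetry and MPA polygons so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ncdf4,
    jsonlite,
    sp,
    igraph,
    geosphere,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
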
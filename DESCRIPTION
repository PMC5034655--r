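Package: ContactGraphKNN
Title: Protein Structure Classification via Contact-Graph Descriptor Embeddings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies protein 3D-structures by converting each structure
    into an alpha-carbon contact graph, embedding the graph into a fixed
    18-dimensional vector of structural and topological descriptors
    (degree, density, clustering, effective eccentricity family, closeness,
    adjacency spectrum, and amino-acid label statistics), and assigning the
    majority class among the k nearest reference vectors under a
    configurable distance measure. Includes min-max-normalized reference
    databases with incremental update, leave-one-out evaluation,
    distance/k sweeps, recursive feature elimination with attribute
    scoring, and a seeded synthetic-structure generator that emulates
    protein families as self-avoiding alpha-carbon backbones.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph, bio3d, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
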
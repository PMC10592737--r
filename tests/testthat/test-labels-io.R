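test_that("generic id normalization accepts the ASCII alias and keeps CGN ids", {
  expect_equal(normalize_generic_id("3x50"), "3×50")
  expect_equal(normalize_generic_id("3×50"), "3×50")
  expect_equal(normalize_generic_id("G.H5.24"), "G.H5.24")
  expect_equal(normalize_generic_id(" 34x51 "), "34×51")
  expect_error(normalize_generic_id(""), "empty")
})

test_that("contact node id formatting and parsing are mutually inverse", {
  ids <- c(contact_node_id("7x55", "G.H5.24"), contact_node_id("34×51", "G.S3.01"))
  parsed <- parse_contact_node_id(ids)
  expect_equal(contact_node_id(parsed$receptor_id, parsed$gprotein_id), ids)
  expect_equal(parsed$receptor_id, c("7×55", "34×51"))
  expect_equal(parsed$gprotein_id, c("G.H5.24", "G.S3.01"))
  expect_error(parse_contact_node_id("nounderscore"), "malformed")
})

test_that("fingerprint write/read round-trips labels and values", {
  fp <- fp_from("3×50_G.H5.23" = c(1, 0), "7×55_G.H5.24" = c(0, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint_table(fp, path)
  back <- read_fingerprint_table(path)
  expect_equal(back$values, fp$values)
  expect_equal(n_frames(back), 2L)
  expect_equal(node_labels(back), node_labels(fp))
})

test_that("malformed fingerprint files are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  expect_error(read_fingerprint_table(path), "empty")
  writeLines(c("a_b\tc_d", "1\t2"), path)
  expect_error(read_fingerprint_table(path), "non-binary.*row 1.*c_d")
  writeLines(c("a_b\ta_b", "1\t0"), path)
  expect_error(read_fingerprint_table(path), "duplicate")
  writeLines(c("a_b\tc_d", "1"), path)
  expect_error(read_fingerprint_table(path), "expected 2")
})

test_that("mapping tables resolve residues and refuse ambiguity", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresid\trole\tgeneric_id",
               "A\t229\treceptor\t5x77",
               "A\t230\treceptor\t5x78",
               "B\t390\tgprotein\tG.H5.24"), path)
  map <- read_mapping_table(path)
  got <- lookup_residue(map, c("A", "B"), c(230, 390))
  expect_equal(got$generic_id, c("5×78", "G.H5.24"))
  expect_error(lookup_residue(map, "A", 999), "absent.*A 999")

  writeLines(c("chain\tresid\trole\tgeneric_id",
               "A\t229\treceptor\t5x77",
               "A\t229\treceptor\t5x78"), path)
  expect_error(read_mapping_table(path), "duplicate")
  writeLines(c("chain\tresid\trole\tgeneric_id", "A\t229\treceptor\t"), path)
  expect_error(read_mapping_table(path), "empty generic_id")
})

test_that("network export writes all formats and GraphML round-trips", {
  fp <- fp_named(cbind(c(1L,0L,1L,0L), c(1L,0L,0L,1L), c(0L,1L,1L,0L)),
                 c("a_b", "c_d", "e_f"))
  net <- contact_bn(fp, data.frame(from = "a_b", to = "c_d"))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "graphml")
  g <- read_network(path)
  expect_setequal(igraph::V(g)$name, net$nodes)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$strength, net$edges$strength)

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(moralize(net), sif, "sif")
  lines <- readLines(sif)
  expect_true(any(grepl("a_b\tlinked\tc_d", lines)))
  expect_true("e_f" %in% lines) # isolated node still listed

  el <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, el, "edgelist")
  tab <- read.delim(el)
  expect_equal(nrow(tab), 1)
  expect_error(write_network(net, el, "dot"), "arg")
})

test_that("empty networks still export valid files", {
  fp <- fp_named(cbind(c(1L, 0L), c(0L, 1L)), c("a_b", "c_d"))
  net <- contact_bn(fp, data.frame(from = character(0), to = character(0)))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "graphml")
  g <- read_network(path)
  expect_equal(igraph::ecount(g), 0)
  expect_setequal(igraph::V(g)$name, c("a_b", "c_d"))
})

test_that("region, conservation and coupling tables parse", {
  rpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("generic_id\tregion", "34x51\tICL2", "G.H5.24\ta5-tip"), rpath)
  regions <- read_region_table(rpath)
  expect_equal(unname(regions["34×51"]), "ICL2")
  writeLines(c("generic_id\tregion", "34x51\tICL2", "34x51\tICL3"), rpath)
  expect_error(read_region_table(rpath), "more than one region")

  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("generic_id\tconserved", "G.H5.24\t1", "G.H5.12\t0"), cpath)
  flags <- read_conservation_table(cpath)
  expect_true(flags[["G.H5.24"]])
  expect_false(flags[["G.H5.12"]])

  kpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region\tdlogEC50", "a5-tip\t-1.5", "b2b3\t-0.4"), kpath)
  expect_equal(read_coupling_table(kpath)[["a5-tip"]], -1.5)
})

test_that("config defaults match the published protocol and validate", {
  cfg <- contactbn_config()
  expect_equal(cfg$salt_bridge_dist, 4.0)
  expect_equal(cfg$hbond_dist, 3.5)
  expect_equal(cfg$hbond_angle, 70)
  expect_equal(cfg$pi_stack_dist, 7.0)
  expect_equal(cfg$pi_stack_angle, 30)
  expect_equal(cfg$cation_pi_dist, 6.0)
  expect_equal(cfg$cation_pi_angle, 60)
  expect_equal(cfg$persistence_threshold, 0.20)
  expect_equal(cfg$restarts, 50)
  expect_equal(cfg$allosteric_cutoff, 10.0)
  expect_equal(cfg$n_perturbations, 1000L)
  expect_equal(cfg$n_resamples, 1000L)
  expect_equal(cfg$ci_level, 0.99)
  expect_equal(cfg$quartile_fraction, 0.25)
  expect_error(contactbn_config(ci_level = 1), "ci_level")
  expect_error(contactbn_config(nonsense = 1), "unknown config")
})
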
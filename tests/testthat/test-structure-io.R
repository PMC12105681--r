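test_that("cluster_model validates sites and fills defaults", {
  m <- cluster_model(data.frame(element = c("Ag", "Ag"), x = c(0, 2.8),
                                y = 0, z = 0))
  expect_s3_class(m, "cluster_model")
  expect_equal(m$label, c("Ag1", "Ag2"))
  expect_equal(m$biso, c(0, 0))
  expect_equal(m$strand, c("none", "none"))

  expect_error(cluster_model(data.frame(element = "Ag", x = 0, y = 0, z = 0)),
               class = "clusterpdf_validation_error")
  expect_error(cluster_model(data.frame(element = c("Ag", "Zz"),
                                        x = c(0, 1), y = 0, z = 0)),
               class = "clusterpdf_validation_error")
  bad <- data.frame(element = c("Ag", "Ag"), x = c(0, 1), y = 0, z = 0,
                    biso = c(-1, 0))
  expect_error(cluster_model(bad), class = "clusterpdf_validation_error")
  dup <- data.frame(element = c("Ag", "Ag"), x = c(0, 1), y = 0, z = 0,
                    label = c("a", "a"))
  expect_error(cluster_model(dup), class = "clusterpdf_validation_error")
})

test_that("XYZ files round-trip and malformed input errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "two silvers", "Ag 0 0 0", "Ag 2.8 0 0"), path)
  m <- read_xyz(path)
  expect_equal(nrow(m), 2)
  expect_equal(m$element, c("Ag", "Ag"))
  expect_equal(as.numeric(dist(coords(m))), 2.8)

  out <- withr::local_tempfile(fileext = ".xyz")
  m2 <- random_model(18, seed = 4, elements = c("Ag", "Cl"))
  write_xyz(m2, out)
  back <- read_xyz(out)
  expect_equal(coords(back), coords(m2), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(back$element, m2$element)

  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(read_xyz(empty), class = "clusterpdf_parse_error")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("not_a_count", "c", "Ag 0 0 0"), bad)
  expect_error(read_xyz(bad), class = "clusterpdf_parse_error")
})

test_that("an 18-row XYZ with 16 Ag + 2 Cl gives the Ag16Cl2 shape", {
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(make_toy_cluster(), path)
  m <- read_xyz(path)
  expect_equal(unname(table(m$element)[c("Ag", "Cl")]), c(16L, 2L),
               ignore_attr = TRUE)
})

test_that("extract_subset selects elements and chains from PDB", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(pdb, n_ag = 3, n_dna = 5)
  ag <- suppressWarnings(extract_subset(pdb, elements = "Ag"))
  expect_equal(nrow(ag), 3)
  expect_equal(unique(ag$element), "Ag")
  expect_equal(sort(as.numeric(dist(coords(ag)))), c(2.8, 2.8, 5.6),
               tolerance = 1e-6)

  dna <- extract_subset(pdb, chains = "A")
  expect_equal(nrow(dna), 5)
  expect_error(extract_subset(pdb, elements = "Xx"),
               class = "clusterpdf_empty_selection_error")
  expect_error(extract_subset(pdb), class = "clusterpdf_validation_error")
})

test_that("extract_subset on a synthetic mmCIF recovers 16 Ag + 2 Cl", {
  cif <- withr::local_tempfile(fileext = ".cif")
  toy <- make_toy_cluster()
  write_toy_cif(cif, toy)
  # independent count directly from the fixture text
  txt <- readLines(cif)
  expect_equal(sum(grepl("^HETATM \\d+ AG ", txt)), 16)
  expect_equal(sum(grepl("^HETATM \\d+ CL ", txt)), 2)

  core <- suppressWarnings(extract_subset(cif, elements = c("Ag", "Cl")))
  expect_equal(nrow(core), 18)
  expect_equal(unname(table(core$element)[c("Ag", "Cl")]), c(16L, 2L),
               ignore_attr = TRUE)
  expect_equal(sort(as.numeric(dist(coords(core)))),
               sort(as.numeric(dist(coords(toy)))), tolerance = 1e-3)
})

test_that("gr files round-trip to 1e-6 and reject bad input", {
  rg <- default_rgrid(0, 30)
  set.seed(1)
  curve <- pdf_curve(rg, rnorm(length(rg)))
  path <- withr::local_tempfile(fileext = ".gr")
  write_gr(curve, path)
  back <- read_gr(path)
  expect_lt(max(abs(back$r - curve$r)), 1e-6)
  expect_lt(max(abs(back$g - curve$g)), 1e-6)

  small <- withr::local_tempfile(fileext = ".gr")
  writeLines(c("# comment", "0.0 0.0", "0.01 0.1"), small)
  expect_equal(nrow(read_gr(small)), 2)

  shuffled <- withr::local_tempfile(fileext = ".gr")
  writeLines(c("0.02 0.1", "0.00 0.0", "0.01 0.3"), shuffled)
  expect_error(read_gr(shuffled), class = "clusterpdf_validation_error")

  junk <- withr::local_tempfile(fileext = ".gr")
  writeLines(c("0.0 zero", "0.01 0.1"), junk)
  expect_error(read_gr(junk), class = "clusterpdf_parse_error")
})

test_that("strand maps read, validate and apply", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,strand_tag", "Ag1,A", "Ag2,B"), path)
  map <- read_strand_map(path)
  expect_equal(unname(map[c("Ag1", "Ag2")]), c("A", "B"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,strand_tag", "Ag1,C"), bad)
  expect_error(read_strand_map(bad), class = "clusterpdf_validation_error")

  m <- two_atom_model()
  m2 <- apply_strand_map(m, map)
  expect_equal(m2$strand, c("A", "B"))
  expect_error(apply_strand_map(m, map["Ag1"]),
               class = "clusterpdf_key_error")
})

test_that("an 8/8 strand split yields two groups of 8 downstream", {
  toy <- make_toy_cluster()
  map <- setNames(c(rep("A", 8), rep("B", 8), "none", "none"), toy$label)
  toy <- apply_strand_map(toy, map)
  gt <- apply_distortion(toy, c(5, 5, -5, -5), jitter = 0, seed = 1)
  stats <- channel_stats(gt$displacement, grouping = "strand")
  expect_equal(sort(stats$n), c(8L, 8L))
})
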
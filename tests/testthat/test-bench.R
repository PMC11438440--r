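test_that("the routine grid enumerates 6 routines and 252 cells for 21 samples", {
  routines <- enumerate_routines()
  expect_equal(nrow(routines), 6L)
  expect_equal(nrow(dplyr::distinct(routines)), 6L)
  expect_setequal(unique(routines$data_type),
                  c("WGS", "panel-filtered", "reference-filtered"))
  expect_setequal(unique(routines$assembler), c("de_novo", "reference_guided"))
  expect_equal(nrow(enumerate_routines(polish_states = TRUE)), 12L)
  expect_equal(nrow(benchmark_grid(sprintf("s%02d", 1:21))), 252L)
})

test_that("run_benchmark fills every grid cell and never silently drops one", {
  fx <- fx_bundle(n_samples = 2)
  bench <- fx_bench2()
  cells <- bench$cells
  expect_equal(nrow(cells), 2L * 6L * 2L)
  expect_true(all(!is.na(cells$status)))
  grid <- benchmark_grid(unique(cells$run_id))
  joined <- dplyr::anti_join(grid, cells,
                             by = c("run_id", "data_type", "assembler",
                                    "polished"))
  expect_equal(nrow(joined), 0L)
  # provenance completeness: exactly 6 routines appear
  expect_equal(nrow(dplyr::distinct(cells[, c("data_type", "assembler")])), 6L)
  # depth ordering: filtered-data assemblies are at least as deep as WGS
  asm <- cells[cells$status == "assembled" & !cells$polished, ]
  wgs <- asm$mean_depth[asm$data_type == "WGS"]
  filt <- asm$mean_depth[asm$data_type != "WGS"]
  if (length(wgs) && length(filt)) expect_gte(max(filt), max(wgs) - 1e-9)
  # identification rows exist for every sample
  expect_equal(sort(unique(bench$identifications$run_id)),
               sort(unique(cells$run_id)))
})

test_that("a sample with zero mitochondrial reads yields explicit failures", {
  fx <- fx_bundle(n_samples = 2)
  run <- fx_skim_run(seed = 57, yield = 3e5, mt_fraction = 1e-6)
  sample0 <- list(run_id = "empty-run", reads = run$reads,
                  truth = c(species = "ghost sp", genus = "Ghost"),
                  reference = fx_close_ref(), scopes = "Metazoa")
  bench <- run_benchmark(list(sample0), fx$panel, fx$database)
  cells <- bench$cells
  filtered_cells <- cells[cells$data_type != "WGS", ]
  expect_true(all(filtered_cells$status == "not_assembled"))
  expect_true(all(bench$identifications$no_identification))
})

test_that("aggregates are an exact function of the cell grid", {
  fx <- fx_bundle(n_samples = 2)
  bench <- fx_bench2()
  agg <- aggregate_quality(bench, yield_boundary = 5e5)
  # double-entry tally with independent base-R arithmetic
  cells <- bench$cells
  key <- paste(cells$assembler,
               ifelse(cells$yield_bases >= 5e5, "high", "low"),
               cells$data_type)
  manual <- tapply(cells$status == "assembled", key, mean) * 100
  got <- setNames(agg$percent_assembled$percent_assembled,
                  paste(agg$percent_assembled$assembler,
                        agg$percent_assembled$yield_class,
                        agg$percent_assembled$data_type))
  expect_equal(got[names(manual)], manual[names(manual)], ignore_attr = TRUE)
  # all-assembled subsets read 100%
  guided <- agg$percent_assembled[
    agg$percent_assembled$assembler == "reference_guided", ]
  expect_true(all(guided$percent_assembled == 100))
})

test_that("the de novo arm fails below the yield boundary while guided holds", {
  # constructed cells straddling a scaled yield boundary: the qualitative
  # low-yield pattern (de novo assembles only with enough data)
  cells <- tidyr::expand_grid(run_id = sprintf("s%d", 1:8),
                              enumerate_routines(polish_states = TRUE))
  cells$yield_bases <- ifelse(as.integer(sub("s", "", cells$run_id)) <= 4,
                              2e5, 2e6)
  cells$status <- ifelse(cells$assembler == "de_novo" &
                           cells$yield_bases < 1e6,
                         "not_assembled", "assembled")
  cells$hit_count <- ifelse(cells$status == "assembled", 35L, NA_integer_)
  cells$error_count <- ifelse(cells$status == "assembled", 2L, NA_integer_)
  cells$complete_cds <- 13L
  cells$complete_rna <- 22L
  cells$stop_codon <- 1L
  cells$incomplete <- 1L
  cells$null <- 0L
  cells$mean_depth <- 5
  agg <- aggregate_quality(cells, yield_boundary = 1e6)
  pa <- agg$percent_assembled
  dn_low <- pa$percent_assembled[pa$assembler == "de_novo" &
                                   pa$yield_class == "low"]
  dn_high <- pa$percent_assembled[pa$assembler == "de_novo" &
                                    pa$yield_class == "high"]
  rg <- pa$percent_assembled[pa$assembler == "reference_guided"]
  expect_true(all(dn_low < dn_high))
  expect_true(all(rg == 100))
})

test_that("recovery summaries are exact sample arithmetic", {
  ids <- tibble::tibble(
    run_id = sprintf("s%d", 1:10), scope = "Metazoa",
    top_species = c(rep("right sp", 9), "wrong sp"),
    top_genus = rep("Right", 10),
    true_species = "right sp", true_genus = "Right",
    no_identification = FALSE)
  rec <- recovery_report(ids)
  expect_equal(rec$percent_correct_genus, 100)
  expect_equal(rec$percent_correct_species, 90)
  ids$top_species <- ids$true_species
  ids$top_genus <- ids$true_genus
  rec2 <- recovery_report(ids)
  expect_equal(rec2$percent_correct_species, 100)
})

test_that("benchmark reruns are deterministic", {
  fx <- fx_bundle(n_samples = 2)
  bench <- fx_bench2()
  again <- run_benchmark(fx$samples[1:2], fx$panel, fx$database,
                         scopes = c("Metazoa"))
  expect_equal(bench$cells, again$cells)
  expect_equal(bench$identifications[names(bench$identifications) != "seconds"],
               again$identifications[names(again$identifications) != "seconds"])
})

test_that("run configurations resolve defaults and reject unknown keys", {
  cfg <- parse_run_config(NULL)
  expect_equal(cfg$min_identity, 90)
  cfg2 <- parse_run_config(list(min_identity = 85, n_samples = 2))
  expect_equal(cfg2$min_identity, 85)
  expect_equal(cfg2$seed, 1L)
  expect_error(parse_run_config(list(minident = 85)), "unknown config key")
  expect_error(parse_run_config(list(min_identity = 101)), "min_identity")
  # key=value file round trip
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "n_samples=2", "target_yield=5e5"), path)
  cfg3 <- parse_run_config(path)
  expect_equal(cfg3$n_samples, 2)
  expect_equal(cfg3$target_yield, 5e5)
  # JSON file
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 9, n_panel = 4), pj, auto_unbox = TRUE)
  expect_equal(parse_run_config(pj)$n_panel, 4)
})

test_that("fixture bundles are deterministic and internally consistent", {
  fx <- fx_bundle(n_samples = 2)
  # taxonomy covers every database record
  expect_setequal(names(fx$database$records), fx$database$taxonomy$record_id)
  # one sample's species is deliberately absent from the database
  present <- vapply(fx$samples, function(s)
    s$truth[["species"]] %in% fx$database$taxonomy$species, TRUE)
  expect_false(present[1])
  expect_true(all(present[-1]))
  # determinism of the bundle under the master seed
  again <- make_fixtures(list(seed = 42, n_samples = 2, target_yield = 1e6))
  expect_identical(fx$samples[[2]]$reads$sequence,
                   again$samples[[2]]$reads$sequence)
  expect_identical(names(fx$database$records), names(again$database$records))
})
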
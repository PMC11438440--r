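# Configuration handling and the default synthetic benchmark bundle:
# sample species across synthetic orders, a scoped identification database,
# a model-organism-style filter panel, and per-sample skim runs - all
# deterministic under one master seed with a documented per-stage
# derivation.

RUN_CONFIG_DEFAULTS <- list(
  seed = 1L,
  n_samples = 3L,
  n_database = 60L,
  n_panel = 10L,
  target_yield = 2e6,
  mean_read_length = 2000,
  per_base_error = 0.05,
  mt_fraction = 0.04,
  q_pass_fraction = 0.82,
  min_identity = 90,
  min_aligned = 100L,
  genome_length = 16500L,
  yield_boundary = 1.5e6
)

#' Parse and validate a run configuration
#'
#' Accepts a named list, a JSON file, or a `key=value` file. Unknown keys
#' are rejected by name; every parameter has a documented default
#' (see `mitoskim:::RUN_CONFIG_DEFAULTS`).
#'
#' @param config `NULL`, a named list of overrides, or a path to a JSON /
#'   `key=value` file.
#' @return the fully resolved configuration list.
#' @export
parse_run_config <- function(config = NULL) {
  overrides <- list()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    txt <- readLines(config, warn = FALSE)
    overrides <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
      jsonlite::fromJSON(paste(txt, collapse = "\n"))
    } else {
      kv <- txt[grepl("=", txt, fixed = TRUE) & !grepl("^\\s*#", txt)]
      keys <- trimws(sub("=.*$", "", kv))
      vals <- trimws(sub("^[^=]*=", "", kv))
      setNames(lapply(vals, function(v) {
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num else v
      }), keys)
    }
  } else if (is.list(config)) {
    overrides <- config
  } else if (!is.null(config)) {
    abort("config must be NULL, a named list, or a file path")
  }
  unknown <- setdiff(names(overrides), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(RUN_CONFIG_DEFAULTS, overrides)
  if (out$min_identity < 0 || out$min_identity > 100) {
    abort("min_identity must be in [0, 100]")
  }
  if (out$per_base_error < 0 || out$per_base_error > 0.5) {
    abort("per_base_error must be in [0, 0.5]")
  }
  if (out$mt_fraction <= 0 || out$mt_fraction >= 1) {
    abort("mt_fraction must be in (0, 1)")
  }
  out
}

synthetic_lineage <- function(order_i, family_i, genus_i, species_i) {
  c(species = sprintf("species o%df%dg%ds%d", order_i, family_i, genus_i, species_i),
    genus = sprintf("Genus-o%df%dg%d", order_i, family_i, genus_i),
    family = sprintf("Familidae-o%df%d", order_i, family_i),
    order = sprintf("Ordiformes-o%d", order_i),
    class = "Mammalia", phylum = "Chordata")
}

#' Build the default synthetic benchmark bundle
#'
#' Generates, deterministically under one master seed: an ancestral
#' mitogenome; an identification database of `n_database` records spread
#' over 3 synthetic orders (2 families each, several genera, congeneric
#' species 2-4% diverged); a filter panel of `n_panel` strongly diverged
#' mitogenomes (model-organism style); and `n_samples` sample species with
#' simulated skim runs, a close reference (a congener), and truth labels.
#' One sample's species is deliberately absent from the database, so its
#' correct identification is the nearest congener (genus right, species
#' wrong).
#'
#' @param config a [parse_run_config()] result or override list.
#' @param out_dir optional directory; when given, the bundle is also written
#'   as FASTA/TSV/FASTQ files.
#' @return list with `database` (`mito_refdb`), `panel` (`mito_refdb`),
#'   `samples` (list of `run_id`, `reads`, `truth`, `reference`, `scopes`,
#'   `sim_truth`), and `config`.
#' @export
make_fixtures <- function(config = NULL, out_dir = NULL) {
  cfg <- parse_run_config(config)
  master <- as.integer(cfg$seed)
  ancestor <- build_mitogenome(derive_seed(master, "ancestor"),
                               length = cfg$genome_length)

  # --- identification database: a hierarchical synthetic taxonomy.
  # Backbones are derived along the tree (ancestor -> order -> family ->
  # genus -> species), so within-rank distances are realistic: congeners a
  # few percent apart, confamilial genera ~5-8%, orders >15%.
  n_db <- cfg$n_database
  db_records <- vector("list", n_db)
  slots <- tibble(
    order_i = rep(1:3, length.out = n_db),
    family_i = rep(rep(1:2, each = 3L), length.out = n_db)
  )
  slots$genus_i <- ((seq_len(n_db) - 1L) %/% 6L) %% 4L + 1L
  slots$species_i <- ((seq_len(n_db) - 1L) %/% 24L) + 1L
  backbone <- new.env(parent = emptyenv())
  bb <- function(key, parent, div) {
    if (is.null(backbone[[key]])) {
      backbone[[key]] <- mutate_genome(parent, div,
                                       derive_seed(master, paste0("bb-", key)),
                                       record_id = paste0("bb-", key))
    }
    backbone[[key]]
  }
  for (i in seq_len(n_db)) {
    o <- slots$order_i[i]; f <- slots$family_i[i]; g <- slots$genus_i[i]
    ord <- bb(sprintf("o%d", o), ancestor, 0.08 + 0.01 * o)
    fam <- bb(sprintf("o%d-f%d", o, f), ord, 0.04)
    gen <- bb(sprintf("o%d-f%d-g%d", o, f, g), fam, 0.022 + 0.002 * g)
    lin <- synthetic_lineage(o, f, g, slots$species_i[i])
    db_records[[i]] <- mutate_genome(
      gen, 0.012 + 0.004 * (slots$species_i[i] - 1L),
      derive_seed(master, paste0("db-", i)),
      lineage = lin, record_id = sprintf("db-%03d", i))
  }
  database <- reference_db(db_records)

  # --- filter panel: one representative near each order/family backbone
  # (a broad panel whose nearest member sits ~4-6% from any sample, the
  # regime the 90% recruitment cutoff was derived for), padded with more
  # distant genomes up to n_panel
  fam_keys <- grep("^o[0-9]+-f[0-9]+$", ls(backbone), value = TRUE)
  panel_records <- vector("list", cfg$n_panel)
  for (i in seq_len(cfg$n_panel)) {
    src <- if (i <= length(fam_keys)) backbone[[fam_keys[i]]] else ancestor
    div <- if (i <= length(fam_keys)) 0.002 else 0.03 + 0.01 * i
    panel_records[[i]] <- mutate_genome(
      src, div, derive_seed(master, paste0("panel-", i)),
      lineage = c(species = paste0("panelia modelus", i),
                  genus = paste0("Panelia", i),
                  family = "Panelidae", order = "Paneliformes",
                  class = "Mammalia", phylum = "Chordata"),
      record_id = sprintf("panel-%02d", i))
  }
  panel <- reference_db(panel_records)

  # --- samples: species tied to database genera; sample 1 is absent from
  # the database (congener-only identification scenario)
  # pool sized so nuclear k-mer depth stays ~1 at the configured yield
  nuclear <- make_nuclear_pool(n = 4L,
                               length = max(2e5, ceiling(cfg$target_yield / 2)),
                               seed = derive_seed(master, "nuclear"))
  samples <- vector("list", cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    db_idx <- ((i - 1L) * 7L) %% n_db + 1L
    rel <- db_records[[db_idx]]
    lin <- rel$lineage
    if (i == 1L) {
      # true species absent from the database: a 2%-diverged congener of rel
      lin["species"] <- paste0(lin["species"], " novus")
      truth_genome <- mutate_genome(rel, 0.02,
                                    derive_seed(master, paste0("sample-", i)),
                                    lineage = lin,
                                    record_id = sprintf("sample-%02d", i))
    } else {
      # true species present: resequence the database species (small
      # intraspecific distance)
      truth_genome <- mutate_genome(rel, 0.003,
                                    derive_seed(master, paste0("sample-", i)),
                                    lineage = lin,
                                    record_id = sprintf("sample-%02d", i))
    }
    cfg_run <- sim_config(seed = derive_seed(master, paste0("run-", i)),
                          target_yield = cfg$target_yield,
                          mean_read_length = cfg$mean_read_length,
                          per_base_error = cfg$per_base_error,
                          mt_fraction = cfg$mt_fraction,
                          q_pass_fraction = cfg$q_pass_fraction)
    run <- simulate_run(truth_genome, nuclear, cfg_run,
                        run_id = sprintf("simrun-%02d", i))
    samples[[i]] <- list(
      run_id = sprintf("simrun-%02d", i),
      reads = filter_by_qscore(run$reads, 7),
      raw_reads = run$reads,
      sim_truth = run$truth,
      truth = lin[c("species", "genus")],
      truth_genome = truth_genome,
      reference = rel,
      scopes = c("Metazoa", paste0("order:", lin[["order"]]),
                 paste0("family:", lin[["family"]])))
  }

  bundle <- list(database = database, panel = panel, samples = samples,
                 config = cfg)
  if (!is.null(out_dir)) write_fixture_bundle(bundle, out_dir)
  bundle
}

write_fixture_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$database, file.path(out_dir, "database.fasta"))
  write_taxonomy_tsv(bundle$database, file.path(out_dir, "database_taxonomy.tsv"))
  write_annotation_tsv(bundle$database, file.path(out_dir, "database_genes.tsv"))
  write_fasta(bundle$panel, file.path(out_dir, "panel.fasta"))
  for (s in bundle$samples) {
    write_fastq(s$reads, file.path(out_dir, paste0(s$run_id, ".fastq")))
    write_truth_tsv(s$sim_truth, file.path(out_dir, paste0(s$run_id, "_truth.tsv")))
  }
  jsonlite::write_json(bundle$config,
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
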
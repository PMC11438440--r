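# Shared fixtures, built once per session and memoised. Everything is
# generated in code under fixed seeds; no data files are shipped.

.fx_env <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (!exists(key, envir = .fx_env)) assign(key, force(expr), envir = .fx_env)
  get(key, envir = .fx_env)
}

# the reference synthetic mitogenome used across modules
fx_genome <- function() fx_memo("genome", build_mitogenome(42))

# a 3%-diverged congener used as the "closest available reference"
fx_close_ref <- function() {
  fx_memo("close_ref",
          mutate_genome(fx_genome(), 0.03, seed = 421, record_id = "close-ref"))
}

fx_pool <- function() fx_memo("pool", make_nuclear_pool(3, 6e5, seed = 43))

# mitochondrial-only read sets at a target depth
fx_mito_reads <- function(depth, error = 0.05, seed = 1000 + depth,
                          mean_len = 3000) {
  key <- sprintf("mito-d%d-e%g-s%d", depth, error, seed)
  fx_memo(key, {
    g <- fx_genome()
    cfg <- sim_config(seed = seed, target_yield = nchar(g$sequence) * depth,
                      mean_read_length = mean_len, mt_fraction = 0.999,
                      per_base_error = error)
    run <- simulate_run(g, fx_pool(), cfg)
    run$reads[run$truth$origin == "mitochondrial", ] |>
      (\(r) keep_reads_attrs(r, run$reads))()
  })
}

# whole-skim run with truth labels
fx_skim_run <- function(seed = 77, yield = 1e6, mt_fraction = 0.02,
                        error = 0.05) {
  key <- sprintf("skim-s%d-y%g-m%g-e%g", seed, yield, mt_fraction, error)
  fx_memo(key, {
    cfg <- sim_config(seed = seed, target_yield = yield,
                      mean_read_length = 2000, mt_fraction = mt_fraction,
                      per_base_error = error)
    simulate_run(fx_genome(), fx_pool(), cfg)
  })
}

# the default benchmark bundle (used by identifier and acceptance tests):
# 10 sample species over 3 synthetic orders, 60-record database, 10-genome
# panel; sample 1's species is deliberately absent from the database
fx_bundle <- function(n_samples = 10) {
  fx_memo(paste0("bundle-", n_samples),
          make_fixtures(list(seed = 42, n_samples = n_samples,
                             target_yield = 1e6)))
}

# per-sample panel-filtered reads for the bundle, computed once
fx_bundle_filtered <- function(n_samples = 10) {
  fx_memo(paste0("bundle-filtered-", n_samples), {
    fx <- fx_bundle(n_samples)
    lapply(fx$samples, function(s) filter_panel(s$reads, fx$panel)$reads)
  })
}

# error-free mitochondrial reads at ~5X, shared by filter tests
fx_errorfree_d5 <- function() {
  fx_memo("errorfree-d5", {
    cfg <- sim_config(seed = 51, target_yield = 16500 * 5,
                      mean_read_length = 2500, mt_fraction = 0.999,
                      per_base_error = 0)
    run <- simulate_run(fx_genome(), fx_pool(), cfg)
    keep_reads_attrs(run$reads[run$truth$origin == "mitochondrial", ],
                     run$reads)
  })
}

# error-free mitochondrial reads at ~20X (noiseless-assembly fixtures)
fx_errorfree_d20 <- function() {
  fx_memo("errorfree-d20", {
    cfg <- sim_config(seed = 73, target_yield = 16500 * 20,
                      mean_read_length = 3000, mt_fraction = 0.999,
                      per_base_error = 0)
    run <- simulate_run(fx_genome(), fx_pool(), cfg)
    keep_reads_attrs(run$reads[run$truth$origin == "mitochondrial", ],
                     run$reads)
  })
}

# a two-sample benchmark run shared by the bench tests
fx_bench2 <- function() {
  fx_memo("bench2", {
    fx <- fx_bundle(n_samples = 2)
    run_benchmark(fx$samples[1:2], fx$panel, fx$database, scopes = c("Metazoa"))
  })
}

# a small deterministic hits table for ranking tests
fx_hits_pool <- function(n = 50, seed = 7) {
  fx_memo(sprintf("hits-%d-%d", n, seed), {
    withr::with_seed(seed, {
      tibble::tibble(
        query_id = paste0("r", seq_len(n)),
        subject_id = paste0("db-", sample(sprintf("%03d", 1:20), n, TRUE)),
        score = sample(50:500, n, TRUE),
        evalue = 10^-sample(3:40, n, TRUE),
        pident = round(runif(n, 85, 100), 2),
        length = sample(100:2000, n, TRUE))
    })
  })
}
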
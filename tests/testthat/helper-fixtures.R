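# Shared builders for small in-code fixtures.

# Model with a single active process (default structure's kinetics unless
# overridden), with the given rate parameter(s).
single_process_model <- function(process_id, kinetics = NULL, ...) {
  m <- default_model_structure()
  m$active <- m$process_id == process_id
  if (!is.null(kinetics)) m <- set_kinetics(m, process_id, kinetics)
  p <- default_parameters(m)
  vals <- c(...)
  if (length(vals)) p <- set_param_values(p, vals)
  list(model = m, params = p)
}

# A plain mid-sized soil state: labelled NH4+, everything else at natural
# abundance.
base_state <- function(nh4 = 20, nh4_frac = 0.10, no3 = 5, n_lab = 50,
                       n_rec = 900, nh4_ads = 0) {
  soil_state(0, isotope_pool(nh4, nh4_frac), isotope_pool(no3),
             isotope_pool(n_lab), isotope_pool(n_rec),
             isotope_pool(nh4_ads))
}

# Default design around the forestland background.
test_design <- function(...) {
  experiment_design(soil_nh4 = 2.35, soil_no3 = 3.02, soil_tn = 1.45, ...)
}

# Batch-means standard error of a correlated MCMC sample mean.
batch_se <- function(x, n_batches = 50) {
  n <- length(x) %/% n_batches * n_batches
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batches))
  sd(bm) / sqrt(n_batches)
}

# Random active model configuration + state for property tests (uses the
# caller's RNG stream).
random_configuration <- function() {
  m <- default_model_structure()
  m$active <- runif(10) < 0.8
  p <- default_parameters(m)
  k_rows <- p$role == "k" & grepl("\\.k$", p$name)
  p$value[k_rows] <- runif(sum(k_rows), 0, 2)
  zero_rows <- p$name %in% paste0(m$process_id[m$kinetics == "zero"], ".k")
  p$value[zero_rows] <- runif(sum(zero_rows), 0, 3)
  st <- soil_state(0,
                   isotope_pool(runif(1, 5, 30), runif(1, 0.004, 0.10)),
                   isotope_pool(runif(1, 5, 30), runif(1, 0.004, 0.10)),
                   isotope_pool(runif(1, 20, 120)),
                   isotope_pool(runif(1, 400, 1200)),
                   isotope_pool(runif(1, 0, 5)))
  list(model = m, params = p, state = st)
}
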
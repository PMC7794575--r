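#' @useDynLib n15trace, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile t.test ks.test cor.test setNames
#' @importFrom utils read.csv write.csv
NULL

# Canonical pool and process order. All internal numeric representations
# (state vectors, parameter vectors, flux vectors) follow these orders.
POOL_NAMES <- c("nh4", "no3", "n_lab", "n_rec", "nh4_ads")

PROCESS_REGISTRY <- data.frame(
  process_id  = c("M_Nlab", "M_Nrec", "I_NH4_Nlab", "I_NH4_Nrec", "A_NH4",
                  "R_NH4", "O_NH4", "O_Nrec", "D_NO3", "I_NO3"),
  source_pool = c("n_lab", "n_rec", "nh4", "nh4", "nh4",
                  "nh4_ads", "nh4", "n_rec", "no3", "no3"),
  sink_pool   = c("nh4", "nh4", "n_lab", "n_rec", "nh4_ads",
                  "nh4", "no3", "no3", "nh4", "n_rec"),
  description = c(
    "mineralization of labile organic N to NH4+",
    "mineralization of recalcitrant organic N to NH4+",
    "immobilization of NH4+ into labile organic N",
    "immobilization of NH4+ into recalcitrant organic N",
    "adsorption of NH4+ onto cation exchange sites",
    "release of adsorbed NH4+",
    "autotrophic nitrification (NH4+ oxidation to NO3-)",
    "heterotrophic nitrification (recalcitrant organic N to NO3-)",
    "dissimilatory NO3- reduction to NH4+ (DNRA)",
    "immobilization of NO3- into recalcitrant organic N"),
  stringsAsFactors = FALSE)

KINETIC_ORDERS <- c("zero", "first", "michaelis_menten")

#' Process registry of the nitrogen transformation network
#'
#' Returns the ten simultaneously occurring transformation processes of the
#' five-pool soil N model, with their fixed source and sink pools. The pools
#' are NH4+ (`nh4`), NO3- (`no3`), labile organic N (`n_lab`), recalcitrant
#' organic N (`n_rec`) and exchangeable adsorbed NH4+ (`nh4_ads`).
#'
#' @return A data frame with columns `process_id`, `source_pool`, `sink_pool`
#'   and `description`.
#' @export
#' @examples
#' process_table()
process_table <- function() PROCESS_REGISTRY

#' Instantaneous flux of a single kinetic process
#'
#' Evaluates a process rate law at a given substrate amount. Zero-order
#' processes proceed at constant rate `k` while substrate remains (the rate is
#' 0 at zero substrate); first-order rates are `k * S`; Michaelis-Menten rates
#' are `vmax * S / (km + S)`.
#'
#' @param kinetic_order One of `"zero"`, `"first"`, `"michaelis_menten"`.
#' @param params Named list or vector: `k` (zero order, mg N kg-1 day-1;
#'   first order, day-1) or `vmax` (mg N kg-1 day-1) and `km` (mg N kg-1).
#' @param substrate_amount Source-pool N amount, mg N kg-1 (must be >= 0).
#' @return Flux in mg N kg-1 day-1 (always >= 0).
#' @export
#' @examples
#' process_rate("first", list(k = 0.1), 20)            # 2
#' process_rate("michaelis_menten", list(vmax = 10, km = 20), 20)  # 5
process_rate <- function(kinetic_order, params, substrate_amount) {
  kinetic_order <- match.arg(kinetic_order, KINETIC_ORDERS)
  if (!is.numeric(substrate_amount) || length(substrate_amount) != 1 ||
      is.na(substrate_amount) || substrate_amount < 0)
    stop("substrate_amount must be a single nonnegative number")
  params <- as.list(params)
  get_par <- function(nm) {
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v)) stop("missing kinetic parameter '", nm, "'")
    if (v < 0) stop("kinetic parameter '", nm, "' must be >= 0")
    v
  }
  if (substrate_amount == 0) return(0)
  switch(kinetic_order,
    zero  = get_par("k"),
    first = get_par("k") * substrate_amount,
    michaelis_menten = {
      vmax <- get_par("vmax"); km <- get_par("km")
      vmax * substrate_amount / (km + substrate_amount)
    })
}

#' Default kinetic structure of the ten-process model
#'
#' One row per process with an `active` flag and the kinetic order used for
#' it. The default assigns first-order kinetics to the substrate-limited
#' inorganic-N processes and zero-order kinetics to mineralization of the
#' large recalcitrant pool and to heterotrophic nitrification; every
#' assignment can be overridden (see [set_kinetics()]), and AIC-based
#' selection among variants is the intended mechanism for choosing between
#' them on real data.
#'
#' @return Data frame with columns `process_id`, `active`, `kinetics`.
#' @export
default_model_structure <- function() {
  kin <- c(M_Nlab = "first", M_Nrec = "zero", I_NH4_Nlab = "first",
           I_NH4_Nrec = "first", A_NH4 = "first", R_NH4 = "first",
           O_NH4 = "first", O_Nrec = "zero", D_NO3 = "first", I_NO3 = "first")
  data.frame(process_id = PROCESS_REGISTRY$process_id,
             active = TRUE,
             kinetics = unname(kin[PROCESS_REGISTRY$process_id]),
             stringsAsFactors = FALSE)
}

#' @rdname default_model_structure
#' @param model A model-structure data frame.
#' @param process_id Process to modify.
#' @param kinetics New kinetic order for the process.
#' @export
set_kinetics <- function(model, process_id, kinetics) {
  model <- validate_model_structure(model)
  kinetics <- match.arg(kinetics, KINETIC_ORDERS)
  i <- match(process_id, model$process_id)
  if (is.na(i)) stop("unknown process id: ", process_id)
  model$kinetics[i] <- kinetics
  model
}

#' @rdname default_model_structure
#' @param active Logical flag; an inactive process contributes zero flux.
#' @export
set_active <- function(model, process_id, active) {
  model <- validate_model_structure(model)
  i <- match(process_id, model$process_id)
  if (is.na(i)) stop("unknown process id: ", process_id)
  model$active[i] <- isTRUE(active)
  model
}

validate_model_structure <- function(model) {
  if (!is.data.frame(model) ||
      !all(c("process_id", "active", "kinetics") %in% names(model)))
    stop("model structure must have columns process_id, active, kinetics")
  bad <- setdiff(model$process_id, PROCESS_REGISTRY$process_id)
  if (length(bad)) stop("unknown process id: ", paste(bad, collapse = ", "))
  if (anyDuplicated(model$process_id)) stop("duplicated process ids")
  if (!all(model$kinetics %in% KINETIC_ORDERS))
    stop("kinetics must be one of: ", paste(KINETIC_ORDERS, collapse = ", "))
  # reorder to canonical order, absent processes treated as inactive
  i <- match(PROCESS_REGISTRY$process_id, model$process_id)
  out <- data.frame(process_id = PROCESS_REGISTRY$process_id,
                    active = FALSE, kinetics = "first",
                    stringsAsFactors = FALSE)
  ok <- !is.na(i)
  out$active[ok] <- as.logical(model$active[i[ok]])
  out$kinetics[ok] <- model$kinetics[i[ok]]
  out
}

#' Parameter set for a kinetic model structure
#'
#' Builds the free-parameter table for a model structure: one `k` per zero- or
#' first-order process, `vmax` and `km` per Michaelis-Menten process, plus the
#' fittable initial amount of the labile organic N pool (`n_lab0`). Each
#' parameter carries a value and box bounds; the bounds double as the uniform
#' prior of the MCMC sampler.
#'
#' @param model Model structure (see [default_model_structure()]).
#' @param values Optional named numeric vector of starting values
#'   (names like `"O_NH4.k"`, `"n_lab0"`).
#' @param first_order_upper,zero_order_upper,vmax_upper,km_upper,n_lab0_upper
#'   Upper bounds: day-1 for first-order `k`, mg N kg-1 day-1 for zero-order
#'   `k` and `vmax`, mg N kg-1 for `km` and `n_lab0`. Lower bounds are 0
#'   (1e-3 for `km` to keep the rate law well defined).
#' @return Data frame with columns `name`, `process`, `role`, `value`,
#'   `lower`, `upper`.
#' @export
default_parameters <- function(model = default_model_structure(),
                               values = NULL,
                               first_order_upper = 10,
                               zero_order_upper = 30,
                               vmax_upper = 50, km_upper = 500,
                               n_lab0_upper = 200) {
  model <- validate_model_structure(model)
  rows <- list()
  for (i in seq_len(nrow(model))) {
    if (!model$active[i]) next
    pid <- model$process_id[i]
    if (model$kinetics[i] == "michaelis_menten") {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(pid, c(".vmax", ".km")), process = pid,
        role = c("vmax", "km"), value = c(5, 50), lower = c(0, 1e-3),
        upper = c(vmax_upper, km_upper), stringsAsFactors = FALSE)
    } else {
      up <- if (model$kinetics[i] == "zero") zero_order_upper else first_order_upper
      val <- if (model$kinetics[i] == "zero") 1 else 0.1
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(pid, ".k"), process = pid, role = "k", value = val,
        lower = 0, upper = up, stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = "n_lab0", process = NA_character_, role = "init", value = 50,
    lower = 0, upper = n_lab0_upper, stringsAsFactors = FALSE)
  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  if (!is.null(values)) params <- set_param_values(params, values)
  validate_parameters(params)
}

#' @rdname default_parameters
#' @param params A parameter table.
#' @export
set_param_values <- function(params, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  i <- match(names(values), params$name)
  if (anyNA(i)) stop("unknown parameter: ",
                     paste(names(values)[is.na(i)], collapse = ", "))
  params$value[i] <- unname(values)
  params
}

validate_parameters <- function(params) {
  need <- c("name", "process", "role", "value", "lower", "upper")
  if (!is.data.frame(params) || !all(need %in% names(params)))
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  if (any(params$lower < 0)) stop("parameter lower bounds must be >= 0")
  if (any(params$value < params$lower - 1e-12) ||
      any(params$value > params$upper + 1e-12))
    stop("parameter values must lie within [lower, upper]")
  if (any(params$upper < params$lower)) stop("upper bound below lower bound")
  params
}

# Pack a model structure + parameter table into the aligned vectors the C++
# core consumes: kinetic codes, active flags, p1 (k or vmax), p2 (km).
pack_model <- function(model, params) {
  model <- validate_model_structure(model)
  kin <- match(model$kinetics, KINETIC_ORDERS) - 1L
  p1 <- numeric(nrow(model))
  p2 <- numeric(nrow(model))
  for (i in seq_len(nrow(model))) {
    pid <- model$process_id[i]
    if (!model$active[i]) next
    if (model$kinetics[i] == "michaelis_menten") {
      p1[i] <- param_value(params, paste0(pid, ".vmax"))
      p2[i] <- param_value(params, paste0(pid, ".km"))
    } else {
      p1[i] <- param_value(params, paste0(pid, ".k"))
    }
  }
  list(kin = kin, active = model$active, p1 = p1, p2 = p2)
}

param_value <- function(params, name, default = NULL) {
  i <- match(name, params$name)
  if (is.na(i)) {
    if (!is.null(default)) return(default)
    stop("parameter '", name, "' missing from parameter table")
  }
  params$value[i]
}
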
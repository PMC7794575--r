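# Natural abundance of 15N in atmospheric N2, atom percent. All atom% excess
# (APE) values in the package are relative to this baseline.
NATURAL_ABUNDANCE_ATOM_PCT <- 0.3663

TREATMENTS <- c("NH4_labelled", "NO3_labelled")
OBS_POOLS <- c("NH4", "NO3")

#' Isotope pool: total N and 15N atom fraction
#'
#' @param total_n Total pool N, mg N kg-1 dry soil (>= 0).
#' @param frac15 15N atom fraction of the pool, absolute (0..1), not excess.
#' @return List of class `isotope_pool`.
#' @export
isotope_pool <- function(total_n, frac15 = NATURAL_ABUNDANCE_ATOM_PCT / 100) {
  if (!is.finite(total_n) || total_n < 0) stop("total_n must be >= 0")
  if (!is.finite(frac15) || frac15 < 0 || frac15 > 1)
    stop("frac15 must lie in [0, 1]")
  structure(list(total_n = total_n, frac15 = frac15), class = "isotope_pool")
}

#' Full soil state at one time point
#'
#' Amounts and 15N atom fractions of the five N pools.
#'
#' @param time Days since label addition (>= 0).
#' @param nh4,no3,n_lab,n_rec,nh4_ads [isotope_pool()] objects.
#' @return List of class `soil_state`.
#' @export
soil_state <- function(time, nh4, no3, n_lab, n_rec, nh4_ads) {
  pools <- list(nh4 = nh4, no3 = no3, n_lab = n_lab, n_rec = n_rec,
                nh4_ads = nh4_ads)
  for (nm in names(pools))
    if (!inherits(pools[[nm]], "isotope_pool"))
      stop("pool '", nm, "' must be an isotope_pool")
  if (!is.finite(time) || time < 0) stop("time must be >= 0")
  structure(c(list(time = time), pools), class = "soil_state")
}

# soil_state <-> length-10 numeric state vector (totals then 15N amounts)
state_to_vector <- function(state) {
  tot <- vapply(POOL_NAMES, function(p) state[[p]]$total_n, numeric(1))
  n15 <- vapply(POOL_NAMES, function(p) state[[p]]$total_n * state[[p]]$frac15,
                numeric(1))
  c(tot, n15)
}

state_from_vector <- function(y, time) {
  pools <- lapply(seq_along(POOL_NAMES), function(i) {
    tot <- y[i]
    frac <- if (tot > 1e-300) y[5 + i] / tot else NATURAL_ABUNDANCE_ATOM_PCT / 100
    isotope_pool(tot, min(max(frac, 0), 1))
  })
  names(pools) <- POOL_NAMES
  do.call(soil_state, c(list(time = time), pools))
}

#' Design of a paired 15N labelling incubation
#'
#' Describes the dual-labelling tracer experiment: both inorganic species are
#' amended at equal N rates, the 15N label sitting on NH4+ in one treatment
#' and on NO3- in the other, with destructive sampling of replicate flasks at
#' fixed times.
#'
#' @param soil_nh4,soil_no3 Background inorganic N of the unamended soil,
#'   mg N kg-1.
#' @param soil_tn Soil total N, g kg-1 (sets the recalcitrant organic pool).
#' @param amendment_nh4,amendment_no3 Amendment rates, mg N kg-1.
#' @param enrichment_nh4 Atom% excess of the NH4+ label in the NH4-labelled
#'   treatment; `enrichment_no3` likewise for the NO3-labelled treatment.
#' @param sampling_times_h Sampling times, hours after label addition
#'   (strictly increasing, > 0).
#' @param replicates Replicate flasks per treatment and time.
#' @param natural_abundance Baseline 15N atom%, default 0.3663.
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(soil_nh4, soil_no3, soil_tn,
                              amendment_nh4 = 20, amendment_no3 = 20,
                              enrichment_nh4 = 9.44, enrichment_no3 = 9.75,
                              sampling_times_h = c(0.5, 12, 24, 48),
                              replicates = 3,
                              natural_abundance = NATURAL_ABUNDANCE_ATOM_PCT) {
  for (v in c(soil_nh4, soil_no3, soil_tn))
    if (!is.finite(v) || v < 0) stop("soil background values must be >= 0 and present")
  if (amendment_nh4 < 0 || amendment_no3 < 0) stop("amendments must be >= 0")
  for (e in c(enrichment_nh4, enrichment_no3))
    if (e <= 0 || e > 100 - natural_abundance)
      stop("enrichments must lie in (0, 100 - natural_abundance]")
  if (any(diff(sampling_times_h) <= 0) || any(sampling_times_h <= 0))
    stop("sampling times must be strictly increasing and > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(soil_nh4 = soil_nh4, soil_no3 = soil_no3, soil_tn = soil_tn,
                 amendment_nh4 = amendment_nh4, amendment_no3 = amendment_no3,
                 enrichment_nh4 = enrichment_nh4,
                 enrichment_no3 = enrichment_no3,
                 sampling_times_h = sampling_times_h, replicates = replicates,
                 natural_abundance = natural_abundance),
            class = "experiment_design")
}

#' Initial soil state for a labelling treatment
#'
#' Mixes the natural-abundance soil background with the amendment: the
#' labelled species enters at natural abundance plus its atom% excess, the
#' unlabelled species at natural abundance, and each inorganic pool's atom
#' fraction is the amount-weighted mixture. Organic pools start at natural
#' abundance; the adsorbed pool starts empty. The recalcitrant pool is
#' `soil_tn * 1000 - n_lab0 - soil_nh4 - soil_no3` so that unamended soil N
#' sums to TN.
#'
#' @param design An [experiment_design()].
#' @param treatment `"NH4_labelled"` or `"NO3_labelled"`.
#' @param n_lab0 Initial labile organic N, mg N kg-1.
#' @return A [soil_state()] at time 0.
#' @export
#' @examples
#' d <- experiment_design(soil_nh4 = 2.46, soil_no3 = 13.60, soil_tn = 0.90)
#' s <- initial_state_from_design(d, "NH4_labelled", n_lab0 = 40)
#' s$nh4$total_n                                    # 22.46
#' (s$nh4$frac15 * 100) - d$natural_abundance       # ~8.406 APE
initial_state_from_design <- function(design, treatment, n_lab0 = 50) {
  stopifnot(inherits(design, "experiment_design"))
  treatment <- match.arg(treatment, TREATMENTS)
  naf <- design$natural_abundance / 100
  label_frac <- function(ape) naf + ape / 100

  mix <- function(soil_amt, amend_amt, amend_frac) {
    tot <- soil_amt + amend_amt
    frac <- if (tot > 0) (soil_amt * naf + amend_amt * amend_frac) / tot else naf
    isotope_pool(tot, frac)
  }
  nh4_frac <- if (treatment == "NH4_labelled")
    label_frac(design$enrichment_nh4) else naf
  no3_frac <- if (treatment == "NO3_labelled")
    label_frac(design$enrichment_no3) else naf

  n_rec0 <- design$soil_tn * 1000 - n_lab0 - design$soil_nh4 - design$soil_no3
  if (n_rec0 < 0)
    stop("n_lab0 plus inorganic N exceeds soil TN; recalcitrant pool negative")
  soil_state(
    time = 0,
    nh4 = mix(design$soil_nh4, design$amendment_nh4, nh4_frac),
    no3 = mix(design$soil_no3, design$amendment_no3, no3_frac),
    n_lab = isotope_pool(n_lab0, naf),
    n_rec = isotope_pool(n_rec0, naf),
    nh4_ads = isotope_pool(0, naf))
}
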
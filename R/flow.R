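#' Composition of a synthetic flow-cytometry event table
#'
#' Defines the latent class mixture and per-class marker distributions used
#' to emulate the bead-labeling verification experiment: whole blood events
#' are a mix of debris and live leukocytes; leukocytes split into CD115-high
#' monocytes and other cells; monocytes split into Gr1-high (classical) and
#' Gr1-low (non-classical) subsets; intravenously injected beads label a
#' fraction of monocytes (FITC-positive), by default exclusively Gr1-low
#' cells.
#'
#' Default class means are separated by many pooled standard deviations
#' (CD115: monocytes 1000 +/- 100 vs others 200 +/- 100), so rectangular
#' gates recover the planted fractions up to binomial sampling error.
#'
#' @param n_events number of events.
#' @param live_fraction fraction of events that are live leukocytes.
#' @param monocyte_fraction_of_leukocytes fraction of live leukocytes that
#'   are monocytes (default 0.127).
#' @param gr1lo_fraction_of_monocytes fraction of monocytes that are Gr1-low.
#' @param beadpos_fraction_of_monocytes fraction of all monocytes that are
#'   bead-positive Gr1-low (default 0.058).
#' @param beadpos_gr1hi_fraction_of_monocytes fraction of monocytes that are
#'   bead-positive Gr1-high (default 0: very few beads label Gr1-high cells).
#' @param class_params per-class per-channel normal parameters; see the
#'   default for the structure.
#' @return an object of class `flow_composition`.
#' @export
flow_composition <- function(n_events = 10000, live_fraction = 0.9,
                             monocyte_fraction_of_leukocytes = 0.127,
                             gr1lo_fraction_of_monocytes = 0.5,
                             beadpos_fraction_of_monocytes = 0.058,
                             beadpos_gr1hi_fraction_of_monocytes = 0,
                             class_params = NULL) {
  fr <- c(live_fraction, monocyte_fraction_of_leukocytes,
          gr1lo_fraction_of_monocytes, beadpos_fraction_of_monocytes,
          beadpos_gr1hi_fraction_of_monocytes)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]", call. = FALSE)
  if (beadpos_fraction_of_monocytes > gr1lo_fraction_of_monocytes) {
    stop("bead-positive fraction cannot exceed the Gr1-low fraction", call. = FALSE)
  }
  if (beadpos_gr1hi_fraction_of_monocytes > 1 - gr1lo_fraction_of_monocytes) {
    stop("bead-positive Gr1-high fraction cannot exceed the Gr1-high fraction",
         call. = FALSE)
  }
  if (is.null(class_params)) {
    class_params <- list(
      debris            = list(fsc = c(50, 15),  ssc = c(60, 20),  cd115 = c(150, 80),
                               gr1 = c(200, 100), fitc = c(40, 25)),
      nonmono_leukocyte = list(fsc = c(400, 80), ssc = c(300, 80), cd115 = c(200, 100),
                               gr1 = c(500, 150), fitc = c(50, 30)),
      mono_gr1hi        = list(fsc = c(420, 80), ssc = c(250, 80), cd115 = c(1000, 100),
                               gr1 = c(1000, 100), fitc = c(50, 30)),
      mono_gr1lo        = list(fsc = c(420, 80), ssc = c(250, 80), cd115 = c(1000, 100),
                               gr1 = c(200, 100), fitc = c(50, 30)),
      mono_gr1lo_beadpos = list(fsc = c(420, 80), ssc = c(250, 80), cd115 = c(1000, 100),
                               gr1 = c(200, 100), fitc = c(1000, 100)),
      mono_gr1hi_beadpos = list(fsc = c(420, 80), ssc = c(250, 80), cd115 = c(1000, 100),
                               gr1 = c(1000, 100), fitc = c(1000, 100)))
  }
  for (cl in class_params) for (ch in cl) {
    if (ch[2] <= 0) stop("all class sigmas must be > 0", call. = FALSE)
  }
  structure(list(n_events = as.integer(n_events), live_fraction = live_fraction,
                 monocyte_fraction_of_leukocytes = monocyte_fraction_of_leukocytes,
                 gr1lo_fraction_of_monocytes = gr1lo_fraction_of_monocytes,
                 beadpos_fraction_of_monocytes = beadpos_fraction_of_monocytes,
                 beadpos_gr1hi_fraction_of_monocytes = beadpos_gr1hi_fraction_of_monocytes,
                 class_params = class_params),
            class = "flow_composition")
}

flow_class_probs <- function(comp) {
  p_live <- comp$live_fraction
  p_mono <- p_live * comp$monocyte_fraction_of_leukocytes
  p_bead_lo <- p_mono * comp$beadpos_fraction_of_monocytes
  p_bead_hi <- p_mono * comp$beadpos_gr1hi_fraction_of_monocytes
  p_lo <- p_mono * comp$gr1lo_fraction_of_monocytes - p_bead_lo
  p_hi <- p_mono * (1 - comp$gr1lo_fraction_of_monocytes) - p_bead_hi
  c(debris = 1 - p_live,
    nonmono_leukocyte = p_live - p_mono,
    mono_gr1hi = p_hi, mono_gr1lo = p_lo,
    mono_gr1lo_beadpos = p_bead_lo, mono_gr1hi_beadpos = p_bead_hi)
}

#' Generate a synthetic flow-cytometry event table
#'
#' Draws class counts from a multinomial around the composition fractions and
#' marker intensities from the per-class normal distributions. The latent
#' `true_class` column is carried for verification against the gating chain.
#'
#' @param comp a [flow_composition()].
#' @param seed integer seed.
#' @return data frame with columns `fsc`, `ssc`, `cd115`, `gr1`, `fitc`,
#'   `true_class`, one row per event in shuffled order.
#' @export
generate_flow_events <- function(comp, seed = 1) {
  if (!inherits(comp, "flow_composition")) {
    stop("`comp` must be a flow_composition", call. = FALSE)
  }
  probs <- flow_class_probs(comp)
  with_seed(seed, {
    counts <- stats::rmultinom(1, comp$n_events, probs)[, 1]
    rows <- lapply(names(counts), function(cl) {
      n <- counts[[cl]]
      if (n == 0) return(NULL)
      cp <- comp$class_params[[cl]]
      data.frame(fsc = stats::rnorm(n, cp$fsc[1], cp$fsc[2]),
                 ssc = stats::rnorm(n, cp$ssc[1], cp$ssc[2]),
                 cd115 = stats::rnorm(n, cp$cd115[1], cp$cd115[2]),
                 gr1 = stats::rnorm(n, cp$gr1[1], cp$gr1[2]),
                 fitc = stats::rnorm(n, cp$fitc[1], cp$fitc[2]),
                 true_class = cl)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
}

#' Gate parameters for the labeling-verification chain
#'
#' Rectangular live gate in (FSC, SSC) plus scalar thresholds for the CD115
#' monocyte gate, the Gr1 subset split, and FITC bead positivity. Defaults
#' match the default [flow_composition()] class separations.
#'
#' @param fsc_range,ssc_range numeric length-2 bounds of the live gate.
#' @param cd115_threshold,gr1_threshold,fitc_threshold scalar cutoffs.
#' @return an object of class `gate_params`.
#' @export
gate_params <- function(fsc_range = c(150, Inf), ssc_range = c(0, Inf),
                        cd115_threshold = 600, gr1_threshold = 600,
                        fitc_threshold = 400) {
  if (fsc_range[1] >= fsc_range[2] || ssc_range[1] >= ssc_range[2]) {
    stop("live gate ranges must be non-degenerate", call. = FALSE)
  }
  structure(list(fsc_range = fsc_range, ssc_range = ssc_range,
                 cd115_threshold = cd115_threshold,
                 gr1_threshold = gr1_threshold,
                 fitc_threshold = fitc_threshold),
            class = "gate_params")
}

#' Live-cell gate
#'
#' Keeps events whose (FSC, SSC) fall inside the rectangular live gate,
#' removing debris.
#'
#' @param events flow event data frame.
#' @param params a [gate_params()].
#' @return the gated subset (possibly empty).
#' @export
gate_live <- function(events, params = gate_params()) {
  if (!nrow(events)) stop("`events` must be non-empty", call. = FALSE)
  keep <- events$fsc >= params$fsc_range[1] & events$fsc <= params$fsc_range[2] &
    events$ssc >= params$ssc_range[1] & events$ssc <= params$ssc_range[2]
  events[keep, , drop = FALSE]
}

#' Monocyte fraction of gated live leukocytes
#'
#' Monocytes are identified by high CD115 expression among live events.
#'
#' @param live_events output of [gate_live()].
#' @param params a [gate_params()].
#' @return percentage of live events above the CD115 threshold.
#' @export
monocyte_fraction <- function(live_events, params = gate_params()) {
  if (!nrow(live_events)) stop("`live_events` must be non-empty", call. = FALSE)
  100 * mean(live_events$cd115 > params$cd115_threshold)
}

#' Split monocytes into Gr1-high and Gr1-low subsets
#'
#' @param monocyte_events CD115-gated monocyte events.
#' @param params a [gate_params()].
#' @return `list(gr1hi = , gr1lo = )`, a disjoint partition of the input.
#' @export
split_gr1 <- function(monocyte_events, params = gate_params()) {
  hi <- monocyte_events$gr1 > params$gr1_threshold
  list(gr1hi = monocyte_events[hi, , drop = FALSE],
       gr1lo = monocyte_events[!hi, , drop = FALSE])
}

#' Bead-positive Gr1-low fraction
#'
#' Fraction of bead-positive (FITC-high) Gr1-low monocytes, reported as a
#' percentage of either all monocytes (the convention used when quoting
#' labeling efficiency) or of the Gr1-low subset only.
#'
#' @param monocyte_events CD115-gated monocyte events.
#' @param params a [gate_params()].
#' @param denominator `"all_monocytes"` (default) or `"gr1lo"`.
#' @return percentage.
#' @export
bead_positive_fraction <- function(monocyte_events, params = gate_params(),
                                   denominator = c("all_monocytes", "gr1lo")) {
  denominator <- match.arg(denominator)
  parts <- split_gr1(monocyte_events, params)
  npos <- sum(parts$gr1lo$fitc > params$fitc_threshold)
  denom <- if (denominator == "all_monocytes") nrow(monocyte_events) else nrow(parts$gr1lo)
  if (denom == 0) stop("empty denominator population", call. = FALSE)
  100 * npos / denom
}

#' Apply the whole gating chain to an event table
#'
#' Live gate, CD115 monocyte gate, Gr1 split, bead positivity; returns the
#' headline fractions of the verification experiment.
#'
#' @param events flow event data frame.
#' @param params a [gate_params()].
#' @return list with `n_live`, `monocyte_percent`, `n_monocytes`,
#'   `gr1lo_percent_of_monocytes`, `beadpos_gr1lo_percent_of_monocytes`,
#'   `beadpos_gr1hi_percent_of_monocytes`.
#' @export
gate_chain <- function(events, params = gate_params()) {
  live <- gate_live(events, params)
  mono <- live[live$cd115 > params$cd115_threshold, , drop = FALSE]
  parts <- split_gr1(mono, params)
  list(
    n_live = nrow(live),
    monocyte_percent = monocyte_fraction(live, params),
    n_monocytes = nrow(mono),
    gr1lo_percent_of_monocytes = 100 * nrow(parts$gr1lo) / max(nrow(mono), 1),
    beadpos_gr1lo_percent_of_monocytes =
      100 * sum(parts$gr1lo$fitc > params$fitc_threshold) / max(nrow(mono), 1),
    beadpos_gr1hi_percent_of_monocytes =
      100 * sum(parts$gr1hi$fitc > params$fitc_threshold) / max(nrow(mono), 1))
}
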
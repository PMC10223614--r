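# Probiotic intervention: least-squares dose fitting and flux shifts.
#
# The dose m >= 0 of a probiotic taxon k added to an ADHD sample x is
# chosen so the renormalized composition best matches a healthy reference
# c:  minimize || (x + m e_k) / (1 + m) - c ||^2. The objective is
# unimodal in m; it is minimized by bounded golden-section search
# (bracket [0, 5]; implied doses are small, on the order of 0.2).

#' Fit a probiotic dose by least squares
#'
#' @param x relative abundance vector of the sample to treat.
#' @param reference relative abundance vector of the healthy reference
#'   sample (same taxon universe; must include the probiotic).
#' @param probiotic taxon label of the probiotic.
#' @param bracket upper end of the search interval for the dose.
#' @param tol absolute tolerance of the golden-section search.
#' @return fitted dose (added abundance units, >= 0).
#' @export
fit_probiotic_dose <- function(x, reference, probiotic, bracket = 5,
                               tol = 1e-8) {
  if (is.null(names(x)) || is.null(names(reference)) ||
      !setequal(names(x), names(reference))) {
    stop("x and reference must share the same named taxon universe",
         call. = FALSE)
  }
  if (!probiotic %in% names(reference)) {
    stop("unknown probiotic taxon: ", probiotic, call. = FALSE)
  }
  reference <- reference[names(x)]
  ek <- as.numeric(names(x) == probiotic)
  f <- function(m) sum(((x + m * ek) / (1 + m) - reference)^2)
  # golden-section search on [0, bracket]
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- bracket
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  m <- (a + b) / 2
  # the unconstrained bound may pull the minimum to 0
  if (f(0) <= f(m)) 0 else m
}

#' Add a probiotic dose to every sample of a study
#'
#' Increments the probiotic taxon's relative abundance by \code{dose} and
#' renormalizes each row; counts are rescaled at the study depth.
#'
#' @param study a \code{paired_study}.
#' @param taxon probiotic taxon label (must be a study column).
#' @param dose added abundance (>= 0); either a scalar applied to all
#'   samples or a vector with one dose per sample.
#' @return the modified \code{paired_study}.
#' @export
apply_probiotic <- function(study, taxon, dose) {
  stopifnot(inherits(study, "paired_study"))
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  if (!taxon %in% colnames(study$abundance)) {
    stop("unknown probiotic taxon: ", taxon, call. = FALSE)
  }
  dose <- rep_len(dose, nrow(study$abundance))
  for (i in seq_len(nrow(study$abundance))) {
    row <- study$abundance[i, ]
    row[taxon] <- row[taxon] + dose[i]
    study$abundance[i, ] <- row / sum(row)
    study$counts[i, ] <- to_counts(study$abundance[i, ], study$depth)
  }
  study
}

#' Quantify per-metabolite flux shifts of an intervention
#'
#' Percent change \code{100 (post - pre) / |pre|} of the lumen exchange
#' flux of each panel metabolite, with a direction-flip flag when the
#' sign changes across the 1e-6 flux epsilon. Changes are flagged
#' undefined when the pre-intervention flux magnitude is below the
#' epsilon.
#'
#' @param pre,post optimal \code{flux_solution}s of the same community
#'   layout before and after the intervention.
#' @param panel metabolite labels (default: the SCFA and
#'   neurotransmitter-precursor panel).
#' @return data frame: metabolite, pre, post, percent_change, flipped,
#'   status.
#' @export
compare_flux_shift <- function(pre, post,
                               panel = c("acetate", "butyrate",
                                         "propionate", "formate",
                                         "glu_L", "trp_L", "tyr_L",
                                         "phe_L")) {
  stopifnot(inherits(pre, "flux_solution"), inherits(post, "flux_solution"),
            pre$status == "optimal", post$status == "optimal")
  le_pre <- lumen_exchange_fluxes(pre)
  le_post <- lumen_exchange_fluxes(post)
  rows <- lapply(panel, function(met) {
    v0 <- if (met %in% names(le_pre)) le_pre[[met]] else 0
    v1 <- if (met %in% names(le_post)) le_post[[met]] else 0
    defined <- abs(v0) > FLUX_EPSILON
    flipped <- defined && abs(v1) > FLUX_EPSILON && sign(v0) != sign(v1)
    data.frame(metabolite = met, pre = v0, post = v1,
               percent_change = if (defined) 100 * (v1 - v0) / abs(v0)
                                else NA_real_,
               flipped = flipped,
               status = if (defined) "ok" else "undefined",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
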
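#' One Michaelis-Menten reaction record
#'
#' A row of measured quantities for one carrier-coupled enzymatic step:
#' substrate concentration, carrier (coenzyme) concentration, the
#' substrate-carrier dissociation constant, and the pathway flux through the
#' step.  Units are mM and mM/s.
#'
#' @param label enzyme/step name.
#' @param substrate_conc substrate concentration (mM, > 0).
#' @param carrier_conc carrier concentration (mM, > 0).
#' @param dissociation_K dissociation constant (mM, > 0).
#' @param flux flux through the step (mM/s, > 0).
#' @return A list of class \code{mm_record}.
#' @export
mm_record <- function(label, substrate_conc, carrier_conc, dissociation_K, flux) {
  vals <- c(substrate_conc, carrier_conc, dissociation_K, flux)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all numeric fields of an mm_record must be positive")
  structure(list(label = label, substrate_conc = substrate_conc,
                 carrier_conc = carrier_conc,
                 dissociation_K = dissociation_K, flux = flux),
            class = "mm_record")
}

#' Enzyme turnover rate from a flux measurement
#'
#' Inverts the model flux \eqn{v = k [m][c]/(K + [c])} for the turnover
#' rate:
#' \deqn{k = \frac{v\,(K + [c])}{[m]\,[c]}.}
#' In the carrier-saturated limit (K -> 0) this is simply flux over
#' substrate concentration.
#'
#' @param rec an \code{\link{mm_record}}.
#' @return The turnover rate in 1/s, unrounded.
#' @examples
#' turnover_rate(mm_record("GAPDH", 6.0, 8.4, 0.2, 5.0))  # ~0.85 /s
#' @export
turnover_rate <- function(rec) {
  stopifnot(inherits(rec, "mm_record"))
  rec$flux * (rec$dissociation_K + rec$carrier_conc) /
    (rec$substrate_conc * rec$carrier_conc)
}

#' Effective flux after a pathway leak
#'
#' A fraction of the uptake is diverted before the step of interest (for
#' glycolysis, the share entering the pentose phosphate pathway); the
#' effective flux is \code{uptake * (1 - leak_fraction)}.
#'
#' @param uptake uptake rate (mM/s).
#' @param leak_fraction diverted fraction in \code{[0, 1)}.
#' @return The effective flux (mM/s).
#' @examples
#' effective_flux(1.8, 0.20)  # 1.44
#' @export
effective_flux <- function(uptake, leak_fraction) {
  stopifnot(leak_fraction >= 0, leak_fraction < 1)
  uptake * (1 - leak_fraction)
}

#' Pathway turnover rates and predicted noise suppression
#'
#' Estimates the turnover rates of the carrier-consuming and
#' carrier-producing steps of a pathway and the resulting stationary Fano
#' factor of the intermediate metabolite, \code{\link{fano_analytic}}.
#' Internal values are unrounded; the \code{signif_kc}/\code{signif_kp}
#' arguments control the significant figures used for the *reported* rates
#' (and the Fano factor derived from them), matching how such estimates are
#' conventionally quoted.
#'
#' @param consuming,producing \code{\link{mm_record}}s for the two steps.
#' @param signif_kc,signif_kp significant figures for the reported rates.
#' @return List of class \code{ccc_pathway_estimate}: unrounded \code{kc},
#'   \code{kp}, \code{fano}; reported \code{kc_reported},
#'   \code{kp_reported}, \code{fano_reported}.
#' @examples
#' d <- ccc_datasets()
#' pathway_estimate(d$`llactis-fermentation`$consuming,
#'                  d$`llactis-fermentation`$producing)
#' @export
pathway_estimate <- function(consuming, producing,
                             signif_kc = 2, signif_kp = 2) {
  kc <- turnover_rate(consuming)
  kp <- turnover_rate(producing)
  kc_r <- signif(kc, signif_kc)
  kp_r <- signif(kp, signif_kp)
  structure(list(kc = kc, kp = kp, fano = fano_analytic(kc, kp),
                 kc_reported = kc_r, kp_reported = kp_r,
                 fano_reported = signif(fano_analytic(kc_r, kp_r), 2),
                 consuming = consuming$label, producing = producing$label),
            class = "ccc_pathway_estimate")
}

#' @export
print.ccc_pathway_estimate <- function(x, ...) {
  cat(sprintf("kc (%s) = %.4g /s [reported %g]\n",
              x$consuming, x$kc, x$kc_reported))
  cat(sprintf("kp (%s) = %.4g /s [reported %g]\n",
              x$producing, x$kp, x$kp_reported))
  cat(sprintf("predicted Fano factor = %.4g [reported %g]\n",
              x$fano, x$fano_reported))
  invisible(x)
}

#' Bundled pathway datasets
#'
#' The two measured pathway tables shipped with the package: aerobic E. coli
#' glycolysis (PFK consuming ATP, PK regenerating it; the 1.8 mM/s glucose
#' uptake with a 20\% pentose-phosphate leak gives the 1.44 mM/s flux) and
#' anaerobic L. lactis lactic fermentation (GAPDH consuming NAD+, LDH
#' regenerating it).
#'
#' @return Named list with elements \code{ecoli-glycolysis} and
#'   \code{llactis-fermentation}; each holds \code{consuming} and
#'   \code{producing} \code{\link{mm_record}}s, plus (E. coli)
#'   \code{uptake_mM_per_s} and \code{leak_fraction}.
#' @export
ccc_datasets <- function() {
  path <- system.file("extdata", "table1_pathways.tsv", package = "cccsim",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$pathway), function(d) {
    recs <- lapply(seq_len(nrow(d)), function(i)
      mm_record(d$label[i], d$substrate_mM[i], d$carrier_mM[i],
                d$K_mM[i], d$flux_mM_per_s[i]))
    names(recs) <- d$step
    recs
  })
  out$`ecoli-glycolysis`$uptake_mM_per_s <- 1.8
  out$`ecoli-glycolysis`$leak_fraction <- 0.20
  out
}
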
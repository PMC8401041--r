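#' Numeric cutoffs for the classification pipeline
#'
#' Collects every threshold the pipeline consults in one validated object.
#' Defaults: the 96.5\% ANIb species cutoff with a 95--96.5\% ambiguity zone
#' resolved by dDDH at 70\%; the 98\%/100\% rpoD identity screen on a 650-bp
#' marker window; and the ANIb method's fragmentation constants (1020-bp
#' fragments, hits kept at >= 30\% identity and >= 70\% fragment coverage).
#' Group delineation accepts clades at >= 70\% bootstrap support.
#'
#' @param ani_species ANI at or above which two genomes are conspecific (\%).
#' @param ani_ambiguous_low Lower edge of the ANI ambiguity zone (\%).
#' @param ddh_species dDDH species boundary (\%).
#' @param rpod_species rpoD identity above which a strain is a candidate
#'   conspecific (\%).
#' @param rpod_exact rpoD identity treated as a confirmed hit (\%).
#' @param marker_window Marker window length (bp).
#' @param fragment_length ANIb fragment length (bp).
#' @param min_hit_identity Minimum fragment-hit identity retained (\%).
#' @param min_hit_coverage Minimum fraction of a fragment that must align.
#' @param group_support Minimum bootstrap support for a group clade (\%).
#' @return An object of class \code{thresholds}.
#' @export
thresholds <- function(ani_species = 96.5,
                       ani_ambiguous_low = 95.0,
                       ddh_species = 70.0,
                       rpod_species = 98.0,
                       rpod_exact = 100.0,
                       marker_window = 650L,
                       fragment_length = 1020L,
                       min_hit_identity = 30,
                       min_hit_coverage = 0.70,
                       group_support = 70) {
  th <- list(
    ani_species = ani_species,
    ani_ambiguous_low = ani_ambiguous_low,
    ddh_species = ddh_species,
    rpod_species = rpod_species,
    rpod_exact = rpod_exact,
    marker_window = as.integer(marker_window),
    fragment_length = as.integer(fragment_length),
    min_hit_identity = min_hit_identity,
    min_hit_coverage = min_hit_coverage,
    group_support = group_support
  )
  pct <- c("ani_species", "ani_ambiguous_low", "ddh_species", "rpod_species",
           "rpod_exact", "min_hit_identity", "group_support")
  for (p in pct) {
    v <- th[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 100) {
      stop("threshold '", p, "' must be a percentage in [0,100]")
    }
  }
  if (th$ani_ambiguous_low >= th$ani_species) {
    stop("ani_ambiguous_low must be below ani_species")
  }
  if (th$min_hit_coverage < 0 || th$min_hit_coverage > 1) {
    stop("min_hit_coverage must be a fraction in [0,1]")
  }
  if (th$marker_window < 1L || th$fragment_length < 1L) {
    stop("marker_window and fragment_length must be positive")
  }
  structure(th, class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat("<thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
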
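# Differentiation and genome-content summary statistics.

#' Phenotypic divergence between the two subpopulations
#'
#' The headline differentiation measure: the magnitude of the difference
#' between the two subpopulation mean phenotypes. Two populations fixed at
#' opposite optima +1 / -1 have divergence 2; permutations of the same set
#' of genotypes have divergence 0.
#'
#' @param state A split `population_state`.
#' @return Non-negative scalar, phenotype units.
#' @export
phenotypic_divergence <- function(state) {
  if (!is_split(state)) {
    stop("phenotypic divergence requires a split population", call. = FALSE)
  }
  phen <- phenotypes(state)
  abs(mean(phen[state$niche == 1L]) - mean(phen[state$niche == 2L]))
}

# Modal effect value among `vals` (present copies), with `n_absent` votes for
# a virtual effect-0 allele. Ties break to the smallest value (deterministic).
leading_value <- function(vals, n_absent) {
  uv <- unique(c(vals, if (n_absent > 0L) 0))
  if (length(uv) == 0L) return(NA_real_)
  uv <- sort(uv)
  counts <- tabulate(match(vals, uv), nbins = length(uv))
  if (n_absent > 0L) {
    z <- match(0, uv)
    counts[z] <- counts[z] + n_absent
  }
  uv[which.max(counts)]
}

#' Leading allele at a locus within a subpopulation
#'
#' The most frequent allele, where "same allele" means bit-identical effect
#' value (identity by copying: mutation almost surely creates a new value).
#' Absent slots count as votes for a virtual allele of effect zero, so in
#' gene-loss scenarios absence itself can be the leading allele once most of
#' a subpopulation has lost the locus. Exact frequency ties break to the
#' smallest effect value.
#'
#' @param state A `population_state`.
#' @param locus Locus index in `1:L`.
#' @param subpop Subpopulation (niche) index, 1 or 2.
#' @return The leading effect value (0 when absence leads).
#' @export
leading_allele <- function(state, locus, subpop) {
  rows <- rows_of_niche(state, subpop)
  if (length(rows) == 0L) stop("empty subpopulation", call. = FALSE)
  pres <- state$present[rows, locus]
  leading_value(state$effects[rows[pres], locus], sum(!pres))
}

#' Per-locus leading-allele divergence profile
#'
#' For every locus, the divergence `d = |a1 - a2|` between the leading-allele
#' effects of the two subpopulations, summarized by `d_max` (the most
#' diverged locus) and `d_mean` (mean over all `L` loci, including extinct
#' ones, whose leading "allele" is absence = 0 on both sides). The gap
#' between `d_max` and `d_mean` measures how much a single major locus
#' carries the divergence. Loci are reported sorted by decreasing `d`.
#'
#' @param state A split `population_state`.
#' @return A `divergence_profile`: list with `per_locus` (tibble: `locus`,
#'   `leading_1`, `leading_2`, `d`, sorted by decreasing `d`), `d_max` and
#'   `d_mean`.
#' @export
divergence_profile <- function(state) {
  if (!is_split(state)) {
    stop("divergence profile requires a split population", call. = FALSE)
  }
  l <- ncol(state$effects)
  rows1 <- rows_of_niche(state, 1L)
  rows2 <- rows_of_niche(state, 2L)
  a1 <- a2 <- numeric(l)
  for (loc in seq_len(l)) {
    p1 <- state$present[rows1, loc]
    p2 <- state$present[rows2, loc]
    a1[loc] <- leading_value(state$effects[rows1[p1], loc], sum(!p1))
    a2[loc] <- leading_value(state$effects[rows2[p2], loc], sum(!p2))
  }
  d <- abs(a1 - a2)
  ord <- order(d, decreasing = TRUE)
  structure(
    list(
      per_locus = tibble::tibble(locus = ord, leading_1 = a1[ord],
                                 leading_2 = a2[ord], d = d[ord]),
      d_max = max(d),
      d_mean = mean(d)
    ),
    class = "divergence_profile"
  )
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("<divergence_profile> d_max = %.4f, d_mean = %.4f\n",
              x$d_max, x$d_mean))
  print(x$per_locus)
  invisible(x)
}

#' Genome-content statistics
#'
#' Summaries of the flexible genome: `pct_missing` (mean over individuals of
#' the percent of their locus slots that are empty), `n_extant_loci` (loci
#' with at least one copy anywhere in the metapopulation),
#' `copies_per_surviving_locus` (mean number of extant copies over extant
#' loci) and `private_locus_fraction` — the fraction of all `L` loci that
#' are effectively restricted to a single subpopulation, classified by a
#' near-fixation rule: presence frequency at least `private_high` in one
#' subpopulation and at most `private_low` in the other. Private loci
#' shield their phenotypic contribution from gene flow.
#'
#' @param state A `population_state`.
#' @param private_high,private_low Presence-frequency thresholds of the
#'   private-locus rule (defaults 0.95 / 0.05).
#' @return A list of the four statistics (class `genome_content_stats`).
#'   `private_locus_fraction` is `NA` for an unsplit population.
#' @export
genome_content <- function(state, private_high = 0.95, private_low = 0.05) {
  pres <- state$present
  copies <- colSums(pres)
  extant <- copies > 0L
  private <- NA_real_
  if (is_split(state)) {
    f1 <- colMeans(pres[rows_of_niche(state, 1L), , drop = FALSE])
    f2 <- colMeans(pres[rows_of_niche(state, 2L), , drop = FALSE])
    private <- mean((f1 >= private_high & f2 <= private_low) |
                      (f2 >= private_high & f1 <= private_low))
  }
  structure(
    list(
      pct_missing = 100 * mean(!pres),
      n_extant_loci = sum(extant),
      copies_per_surviving_locus =
        if (any(extant)) mean(copies[extant]) else NA_real_,
      private_locus_fraction = private
    ),
    class = "genome_content_stats"
  )
}

#' @export
print.genome_content_stats <- function(x, ...) {
  cat(sprintf(paste0("<genome_content_stats> %.2f%% slots missing, ",
                     "%d extant loci, %.1f copies/surviving locus, ",
                     "private fraction %s\n"),
              x$pct_missing, x$n_extant_loci, x$copies_per_surviving_locus,
              format(x$private_locus_fraction)))
  invisible(x)
}
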
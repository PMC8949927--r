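#' Construct a genetic map for one chromosome
#'
#' A genetic map ties ordered marker names to physical (bp) and genetic (cM)
#' positions on a single chromosome. Both coordinate systems must be strictly
#' increasing along the marker order.
#'
#' @param chrom Chromosome identifier (scalar character).
#' @param marker Character vector of unique marker names.
#' @param pos_bp Integer-ish vector of physical positions (1-based bp).
#' @param pos_cm Numeric vector of genetic positions (centiMorgan, >= 0).
#' @return A `genetic_map` object: a data.frame with columns `marker`,
#'   `chrom`, `pos_bp`, `pos_cm`.
#' @examples
#' gm <- genetic_map("13", c("m1", "m2"), c(1e6, 2e6), c(0, 0.5))
#' @export
genetic_map <- function(chrom, marker, pos_bp, pos_cm) {
  stopifnot(length(chrom) == 1L, length(marker) == length(pos_bp),
            length(pos_bp) == length(pos_cm))
  if (anyDuplicated(marker)) stop("marker names must be unique")
  if (any(pos_cm < 0)) stop("cM positions must be >= 0")
  if (is.unsorted(pos_bp, strictly = TRUE))
    stop("bp positions must be strictly increasing")
  if (is.unsorted(pos_cm, strictly = TRUE))
    stop("cM positions must be strictly increasing")
  out <- data.frame(marker = as.character(marker), chrom = chrom,
                    pos_bp = as.numeric(pos_bp), pos_cm = as.numeric(pos_cm),
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Packaged chromosome 13 fixture map
#'
#' Synthetic marker map for mouse chromosome 13 used by the simulation
#' fixtures: markers every 2 Mbp from 70.0 to 120.0 Mbp plus the peak marker
#' rs4222065 at 112.5 Mbp and a terminal marker at 120.4 Mbp. Genetic
#' positions use a flat 0.5 cM/Mbp conversion, so bp and cM are
#' interchangeable up to a constant.
#'
#' @return A [genetic_map()] for chromosome "13".
#' @export
chr13_map <- function() {
  bp <- sort(unique(c(seq(70e6, 120e6, by = 2e6), 112.5e6, 120.4e6)))
  nm <- sprintf("D13S%03d", round(bp / 1e6 * 10))
  nm[bp == 112.5e6] <- "rs4222065"
  genetic_map("13", nm, bp, bp / 1e6 * 0.5)
}

#' Haldane map function
#'
#' Converts a map distance (Morgan) into a recombination fraction under the
#' no-interference (Poisson crossover) model: `r = (1 - exp(-2 d)) / 2`.
#'
#' @param d Map distance in Morgan (>= 0); vectorized.
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(0)            # 0
#' haldane(0.5)          # (1 - exp(-1)) / 2
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d)) / 2
}

#' @keywords internal
map_span_bp <- function(map) range(map$pos_bp)
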
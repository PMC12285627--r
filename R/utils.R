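#' Derive a component seed from a master seed
#'
#' All randomness in the package flows from one user-supplied seed. Each
#' component (fold assignment, subset sampling, background draws, ...) derives
#' its own stream with a splitmix-style integer hash of the master seed and a
#' component label, so that changing one component never perturbs another.
#'
#' @param seed master seed (single integer).
#' @param label character scalar naming the consuming component.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    # 64-bit-safe modular mix kept inside double precision
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h * 48271) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Weighted median
#'
#' Smallest value at which the cumulative normalized weight reaches one half.
#'
#' @param x numeric values.
#' @param w nonnegative weights, same length as `x`.
#' @return the weighted median of `x`.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

## Internal interval helpers --------------------------------------------------

# Genomic interval constructor used throughout: 0-based half-open coordinates.
# GRanges is 1-based closed, so [start, end) maps to IRanges(start + 1, end).
gi_to_granges <- function(chrom, start, end, strand = "*") {
  stopifnot(all(start < end), all(nzchar(chrom)))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

# Total width of a GRanges in bases.
gr_width_sum <- function(gr) sum(IRanges::width(gr))

# Stack per-gene interval data.frames (chrom/start/end) into one GRanges plus
# the index of the owning gene, so operators can overlap all genes in a single
# call instead of one S4 operation per gene.
stack_regions <- function(region_sets, get_df) {
  dfs <- lapply(region_sets, get_df)
  n_iv <- vapply(dfs, nrow, 0L)
  if (sum(n_iv) == 0L) {
    return(list(gr = GenomicRanges::GRanges(), gene = integer()))
  }
  df <- do.call(rbind, dfs[n_iv > 0L])
  list(gr = gi_to_granges(df$chrom, df$start, df$end),
       gene = rep(seq_along(region_sets), n_iv))
}

# Merge possibly-overlapping 0-based half-open intervals (plain data.frame
# interval arithmetic; single chromosome).
union_intervals <- function(df) {
  rownames(df) <- NULL
  if (nrow(df) < 2L) return(df[, c("start", "end")])
  df <- df[order(df$start), , drop = FALSE]
  e_cum <- cummax(df$end)
  grp <- cumsum(c(TRUE, df$start[-1L] > e_cum[-nrow(df)]))
  data.frame(start = as.numeric(tapply(df$start, grp, min)),
             end = as.numeric(tapply(df$end, grp, max)))
}

# Complement of sorted non-overlapping intervals within [start, end).
complement_within <- function(start, end, ivs) {
  cs <- pmax(ivs$start, start)
  ce <- pmin(ivs$end, end)
  ok <- cs < ce
  cs <- cs[ok]
  ce <- ce[ok]
  starts <- c(start, ce)
  ends <- c(cs, end)
  ok <- starts < ends
  data.frame(start = starts[ok], end = ends[ok])
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
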
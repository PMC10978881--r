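# LD from reference genotypes, LD blocks, block overlap.

#' Squared dosage correlation between two SNPs
#'
#' Genotype r-squared computed from a reference panel's dosages. Undefined
#' (returns `NA` with a warning) when either SNP is monomorphic in the
#' panel — as happens when a lead SNP does not segregate in the alternate
#' ancestry.
#'
#' @param ref A [genotype_set()] reference panel.
#' @param snp_a,snp_b SNP ids (or column indices).
#' @return r-squared in `[0, 1]`, or `NA` if undefined.
#' @export
ld_r2 <- function(ref, snp_a, snp_b) {
  ga <- ref$dosage[, snp_a]
  gb <- ref$dosage[, snp_b]
  if (stats::sd(ga) == 0 || stats::sd(gb) == 0) {
    warning("monomorphic SNP: LD undefined")
    return(NA_real_)
  }
  stats::cor(ga, gb)^2
}

# r2 of one anchor against many candidate columns; NA where monomorphic
ld_r2_vec <- function(ref, anchor, candidates) {
  ga <- ref$dosage[, anchor]
  if (stats::sd(ga) == 0) return(rep(NA_real_, length(candidates)))
  G <- ref$dosage[, candidates, drop = FALSE]
  sds <- apply(G, 2L, stats::sd)
  r2 <- rep(NA_real_, length(candidates))
  ok <- sds > 0
  if (any(ok)) r2[ok] <- as.numeric(stats::cor(ga, G[, ok, drop = FALSE]))^2
  r2
}

#' Build an LD block around an anchor SNP
#'
#' The block is the anchor plus every candidate SNP with panel r-squared
#' above `r2_min` (strict) to the anchor.
#'
#' @param ref A [genotype_set()] reference panel.
#' @param anchor Anchor SNP id.
#' @param candidates Candidate SNP ids (default: all panel SNPs on the
#'   anchor's chromosome).
#' @param r2_min Strict lower r-squared bound (default 0.8).
#' @param panel Label stored on the block (e.g. "EUR").
#' @return List of class `ld_block` with `anchor`, `members`
#'   (`data.frame` snp, r2), `panel`.
#' @export
ld_block <- function(ref, anchor, candidates = NULL, r2_min = 0.8,
                     panel = NA_character_) {
  v <- ref$variants
  a_idx <- match(anchor, v$snp)
  if (is.na(a_idx)) stop("anchor SNP not in panel")
  if (stats::sd(ref$dosage[, a_idx]) == 0)
    stop("anchor SNP is monomorphic in the panel")
  if (is.null(candidates))
    candidates <- v$snp[v$chrom == v$chrom[a_idx]]
  candidates <- setdiff(candidates, anchor)
  r2 <- ld_r2_vec(ref, a_idx, match(candidates, v$snp))
  sel <- which(!is.na(r2) & r2 > r2_min)
  members <- data.frame(snp = c(anchor, candidates[sel]),
                        r2 = c(1, r2[sel]))
  structure(list(anchor = anchor, members = members, panel = panel),
            class = "ld_block")
}

#' Do two LD blocks share a member?
#'
#' @param a,b [ld_block()] objects.
#' @return `TRUE` iff the member SNP sets intersect.
#' @export
blocks_overlap <- function(a, b) {
  length(intersect(a$members$snp, b$members$snp)) > 0
}
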
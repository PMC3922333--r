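#' Call genotypes from allele depths by the proportion rule
#'
#' With `p = ref/(ref+alt)`, a sample is homozygous reference when
#' `p > hi`, homozygous alternative when `p < lo`, heterozygous when `p`
#' lies between the bounds (boundaries inclusive to heterozygous). A
#' provisional homozygote with depth below `min_hom_depth`, a provisional
#' heterozygote with depth below `min_het_depth`, and any zero-depth
#' sample, are recoded as missing. Vectorised: inputs may be vectors or
#' matrices of matching shape.
#'
#' @param ref_depth,alt_depth Non-negative read counts.
#' @param hi,lo Proportion bounds (defaults 0.8 / 0.2).
#' @param min_hom_depth,min_het_depth Minimum depths (defaults 3 / 6).
#' @return Character vector/matrix over
#'   `{"hom_ref","hom_alt","het","missing"}`.
#' @examples
#' callGenotype(c(10, 5, 2, 3), c(0, 5, 0, 2))
#' @export
callGenotype <- function(ref_depth, alt_depth, hi = 0.8, lo = 0.2,
                         min_hom_depth = 3L, min_het_depth = 6L) {
  if (any(ref_depth < 0) || any(alt_depth < 0))
    stop("depths must be non-negative")
  depth <- ref_depth + alt_depth
  p <- ifelse(depth > 0, ref_depth / depth, NA)
  state <- ifelse(is.na(p), "missing",
           ifelse(p > hi, "hom_ref",
           ifelse(p < lo, "hom_alt", "het")))
  hom <- state %in% c("hom_ref", "hom_alt")
  state[hom & depth < min_hom_depth] <- "missing"
  state[state == "het" & depth < min_het_depth] <- "missing"
  if (is.matrix(ref_depth))
    state <- matrix(state, nrow(ref_depth), ncol(ref_depth),
                    dimnames = dimnames(ref_depth))
  state
}

#' Genotype all sites of a SnpRecords object
#'
#' @param snps A [SnpRecords-class].
#' @inheritParams callGenotype
#' @return Character matrix (sites x samples) of proportion-rule states.
#' @export
callGenotypes <- function(snps, hi = 0.8, lo = 0.2, min_hom_depth = 3L,
                          min_het_depth = 6L) {
  stopifnot(is(snps, "SnpRecords"))
  callGenotype(snps@refDepth, snps@altDepth, hi = hi, lo = lo,
               min_hom_depth = min_hom_depth, min_het_depth = min_het_depth)
}

#' Merge replicate sample columns by summing depths
#'
#' Parents sequenced repeatedly across libraries are merged by summing
#' their allele depths before genotype calling.
#'
#' @param snps A [SnpRecords-class].
#' @param sample_map Named character vector mapping each current sample
#'   id to its merged id (identity entries may be omitted).
#' @return A [SnpRecords-class] with merged sample columns.
#' @export
mergeSampleReplicates <- function(snps, sample_map) {
  stopifnot(is(snps, "SnpRecords"))
  new_id <- ifelse(snps@samples %in% names(sample_map),
                   unname(sample_map[snps@samples]), snps@samples)
  groups <- unique(new_id)
  sum_by <- function(m) {
    out <- sapply(groups, function(g)
      rowSums(m[, new_id == g, drop = FALSE]))
    if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(NULL, groups))
    out
  }
  initialize(snps,
             refDepth = sum_by(snps@refDepth),
             altDepth = sum_by(snps@altDepth),
             altQualSum = sum_by(snps@altQualSum),
             samples = groups)
}

#' Recode genotype states to biparental a/b/h coding
#'
#' A marker is retained only when both parents are called homozygous for
#' opposite alleles; progeny homozygote states are then mapped to `"a"`
#' (parent-A allele) or `"b"` (parent-B allele), heterozygotes to `"h"`.
#' Dropped markers carry a reason: `parent-missing`, `parent-het` or
#' `parents-identical`.
#'
#' @param states Character matrix (markers x samples) of proportion-rule
#'   states; markers must be row-named; columns must include both parents.
#' @param parent_a,parent_b Parent sample ids.
#' @param quality Optional per-marker quality scores (default 0).
#' @param info Optional per-marker annotation `data.frame`.
#' @return A list: `genotypes` ([GenotypeMatrix-class], progeny columns
#'   only) and `dropped` (`data.frame`: `marker`, `reason`).
#' @export
recodeParental <- function(states, parent_a, parent_b, quality = NULL,
                           info = NULL) {
  stopifnot(is.matrix(states), !is.null(rownames(states)))
  if (!all(c(parent_a, parent_b) %in% colnames(states)))
    stop("both parents must be columns of the state matrix")
  if (is.null(quality)) quality <- rep(0, nrow(states))
  pa <- states[, parent_a]
  pb <- states[, parent_b]
  reason <- rep(NA_character_, nrow(states))
  reason[pa == "missing" | pb == "missing"] <- "parent-missing"
  hetp <- is.na(reason) & (pa == "het" | pb == "het")
  reason[hetp] <- "parent-het"
  same <- is.na(reason) & pa == pb
  reason[same] <- "parents-identical"
  keep <- is.na(reason)

  prog_cols <- setdiff(colnames(states), c(parent_a, parent_b))
  sub <- states[keep, prog_cols, drop = FALSE]
  a_state <- pa[keep]  # parent A's homozygous state labels the "a" allele
  coded <- matrix(NA_character_, nrow(sub), ncol(sub),
                  dimnames = dimnames(sub))
  for (st in c("hom_ref", "hom_alt")) {
    rows <- a_state == st
    coded[rows, ][sub[rows, , drop = FALSE] == st] <- "a"
    other <- if (st == "hom_ref") "hom_alt" else "hom_ref"
    coded[rows, ][sub[rows, , drop = FALSE] == other] <- "b"
  }
  coded[sub == "het"] <- "h"

  gm <- new("GenotypeMatrix", calls = coded, quality = quality[keep],
            parentA = parent_a, parentB = parent_b,
            info = if (is.null(info)) {
              data.frame(row.names = rownames(sub))
            } else info[keep, , drop = FALSE])
  dropped <- data.frame(marker = rownames(states)[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  list(genotypes = gm, dropped = dropped)
}
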
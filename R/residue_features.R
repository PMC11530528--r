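# Physicochemical residue descriptors used as contact-graph node features.
#
# Seven properties per residue, in this fixed, documented order:
#   1. isoelectric point (pI)
#   2. polarity (Grantham polarity scale)
#   3. acidity/alkalinity class (-1 acidic, 0 neutral, +1 basic at pH 7)
#   4. hydrogen-bond acceptor count (side chain)
#   5. hydrogen-bond donor count (side chain)
#   6. octanol-water partition coefficient (Kyte-Doolittle hydropathy as the
#      bundled partition surrogate)
#   7. topological polar surface area of the side chain (A^2)
#
# Values are bundled reference constants compiled from standard amino-acid
# property tables (pI/polarity: Grantham 1974 and standard pKa tables;
# hydropathy: Kyte & Doolittle 1982; donor/acceptor counts and TPSA from
# standard residue chemistry). Downstream code treats the table as an opaque
# featurizer: tests assert shape and determinism, not individual constants.

RESIDUE_PROPERTY_NAMES <- c("isoelectric_point", "polarity", "acid_base",
                            "hbond_acceptor", "hbond_donor",
                            "partition_coefficient", "tpsa")

RESIDUE_FEATURE_TABLE <- local({
  tab <- rbind(
    A = c(6.00,  8.1,  0, 0, 0,  1.8,   0.0),
    R = c(10.76, 10.5, 1, 3, 4, -4.5, 123.0),
    N = c(5.41, 11.6,  0, 2, 1, -3.5,  63.6),
    D = c(2.77, 13.0, -1, 3, 0, -3.5,  60.4),
    C = c(5.07,  5.5,  0, 0, 1,  2.5,  38.8),
    Q = c(5.65, 10.5,  0, 2, 1, -3.5,  63.6),
    E = c(3.22, 12.3, -1, 3, 0, -3.5,  60.4),
    G = c(5.97,  9.0,  0, 0, 0, -0.4,   0.0),
    H = c(7.59, 10.4,  1, 1, 1, -3.2,  28.7),
    I = c(6.02,  5.2,  0, 0, 0,  4.5,   0.0),
    L = c(5.98,  4.9,  0, 0, 0,  3.8,   0.0),
    K = c(9.74, 11.3,  1, 1, 2, -3.9,  26.0),
    M = c(5.74,  5.7,  0, 0, 0,  1.9,  25.3),
    F = c(5.48,  5.2,  0, 0, 0,  2.8,   0.0),
    P = c(6.30,  8.0,  0, 0, 0, -1.6,   0.0),
    S = c(5.68,  9.2,  0, 1, 1, -0.8,  20.2),
    T = c(5.60,  8.6,  0, 1, 1, -0.7,  20.2),
    W = c(5.89,  5.4,  0, 0, 1, -0.9,  15.8),
    Y = c(5.66,  6.2,  0, 1, 1, -1.3,  20.2),
    V = c(5.96,  5.9,  0, 0, 0,  4.2,   0.0))
  colnames(tab) <- RESIDUE_PROPERTY_NAMES
  tab
})

#' The bundled residue physicochemical feature table
#'
#' Returns the 20 x 7 matrix of per-residue descriptors (isoelectric point,
#' polarity, acidity/alkalinity, hydrogen-bond acceptor and donor counts,
#' octanol-water partition surrogate, topological polar surface area) keyed by
#' one-letter amino-acid code. Column order is fixed and documented in the
#' package source.
#'
#' @return Numeric matrix with rownames `A`..`V` and 7 named columns.
#' @export
residue_feature_table <- function() RESIDUE_FEATURE_TABLE

#' Featurize a residue sequence
#'
#' Maps each one-letter residue code to its 7-vector of physicochemical
#' properties from [residue_feature_table()]. Non-standard codes get a zero
#' row plus a warning (real chains contain them; rejection would be
#' unhelpful).
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @param table Feature table; defaults to the bundled constants.
#' @return Numeric matrix `L x 7`.
#' @export
featurize_residues <- function(sequence, table = residue_feature_table()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("featurize_residues: sequence must be a nonempty character scalar")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  idx <- match(chars, rownames(table))
  out <- matrix(0, length(chars), ncol(table))
  hit <- !is.na(idx)
  out[hit, ] <- table[idx[hit], , drop = FALSE]
  if (any(!hit)) {
    warning(sprintf("featurize_residues: %d non-standard residue code(s) (%s) given zero features",
                    sum(!hit), paste(unique(chars[!hit]), collapse = ", ")))
  }
  colnames(out) <- colnames(table)
  out
}
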
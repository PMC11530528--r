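# Drug graphs from SMILES. R has no cheminformatics toolkit in this package's
# dependency set, so parsing is delegated to the rdkit installation of the
# `python` on PATH through a small bundled script; only the resulting
# atom/bond table crosses the language boundary (as JSON).

ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Build a drug molecular graph from a SMILES line notation
#'
#' Parses the SMILES with rdkit (via the bundled Python helper) into a
#' hydrogen-suppressed atom graph. Node features are the element one-hot over
#' a fixed vocabulary (C, N, O, S, P, F, Cl, Br, I, other), heavy-atom
#' degree, formal charge and an aromaticity flag (13 columns); edge features
#' are a bond-order one-hot (single, double, triple, aromatic).
#'
#' @param smiles A SMILES string.
#' @param entity_id Identifier stored on the graph (defaults to the SMILES).
#' @param python Python interpreter to invoke; must have rdkit installed.
#' @return A [molecular_graph()] with `entity_kind = "drug"`.
#' @export
molecular_graph_from_line_notation <- function(smiles, entity_id = smiles,
                                               python = "python") {
  script <- system.file("python", "smiles_to_graph.py", package = "muse")
  if (script == "") stop("molecular_graph_from_line_notation: bundled parser script not found")
  out <- suppressWarnings(
    system2(python, c(shQuote(script), shQuote(smiles)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop(sprintf("molecular_graph_from_line_notation: cannot parse '%s' (%s)",
                 smiles, paste(out, collapse = "; ")))
  }
  obj <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyDataFrame = TRUE)
  atoms <- obj$atoms
  n <- nrow(atoms)
  if (is.null(n) || n == 0L) {
    stop(sprintf("molecular_graph_from_line_notation: '%s' has no heavy atoms", smiles))
  }
  elem <- match(atoms$symbol, ELEMENT_VOCAB)
  onehot <- matrix(0, n, length(ELEMENT_VOCAB) + 1L)
  for (r in seq_len(n)) {
    col <- if (is.na(elem[r])) length(ELEMENT_VOCAB) + 1L else elem[r]
    onehot[r, col] <- 1
  }
  node_features <- cbind(onehot, atoms$degree, atoms$formal_charge, atoms$aromatic)
  colnames(node_features) <- c(ELEMENT_VOCAB, "other", "degree",
                               "formal_charge", "aromatic")
  bonds <- obj$bonds
  if (length(bonds) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
    edge_features <- NULL
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 3L)
    edges <- bonds[, 1:2, drop = FALSE]
    edge_features <- matrix(0, nrow(bonds), 4L)
    edge_features[cbind(seq_len(nrow(bonds)), bonds[, 3L] + 1L)] <- 1
    colnames(edge_features) <- c("single", "double", "triple", "aromatic")
  }
  molecular_graph(entity_id, "drug", node_features = node_features,
                  edges = edges, edge_features = edge_features)
}
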
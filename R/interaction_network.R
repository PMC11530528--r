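#' Define the label space of an interaction network
#'
#' @param type `"binary"` (single sigmoid class), `"multilabel"` (independent
#'   sigmoid per interaction type) or `"multiclass"` (one softmax over types).
#' @param classes Character vector of class names; for `"binary"` a single
#'   name (default `"interaction"`).
#' @return A `muse_label_space` list with elements `type`, `classes`,
#'   `n_classes`.
#' @export
label_space <- function(type = c("binary", "multilabel", "multiclass"),
                        classes = NULL) {
  type <- match.arg(type)
  if (is.null(classes)) {
    classes <- if (type == "binary") "interaction" else
      stop("label_space: classes must be given for multilabel/multiclass")
  }
  if (type == "binary" && length(classes) != 1L) {
    stop("label_space: binary label space has exactly one class")
  }
  structure(list(type = type, classes = as.character(classes),
                 n_classes = length(classes)),
            class = "muse_label_space")
}

#' Construct an interaction network
#'
#' The molecular-network-scale container: an ordered entity list plus labeled
#' links. Each link carries a label vector in `[0,1]^C`, a provenance `status`
#' (`observed`, `unobserved`, `pseudo`) and a confidence. The network
#' adjacency A is the symmetric 0/1 matrix with `A[i,j] = 1` iff the pair has
#' status `observed` or `pseudo`; `unobserved` links are the held-out pairs
#' whose labels the models predict.
#'
#' @param entity_ids Character vector of unique entity identifiers; link
#'   indices refer to positions in this vector (1-based).
#' @param space A [label_space()].
#' @param links Data frame with integer columns `i`, `j`, character `status`,
#'   numeric `confidence`.
#' @param labels Numeric matrix with `nrow(links)` rows and one column per
#'   class, entries in `[0,1]`.
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(entity_ids, space, links, labels) {
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stop("interaction_network: duplicate entity ids")
  stopifnot(inherits(space, "muse_label_space"))
  links <- as.data.frame(links)
  labels <- matrix(as.numeric(labels), nrow = nrow(links), ncol = space$n_classes)
  N <- length(entity_ids)
  if (nrow(links) > 0L) {
    if (any(links$i < 1L | links$i > N | links$j < 1L | links$j > N)) {
      stop("interaction_network: link index out of range")
    }
    if (any(links$i == links$j)) {
      stop("interaction_network: self-interactions are not allowed")
    }
    ii <- pmin(links$i, links$j); jj <- pmax(links$i, links$j)
    links$i <- ii; links$j <- jj
    if (anyDuplicated(ii * (N + 1) + jj)) {
      stop("interaction_network: duplicate link pair")
    }
    if (!all(links$status %in% c("observed", "unobserved", "pseudo"))) {
      stop("interaction_network: invalid link status")
    }
    if (any(links$status == "observed" & links$confidence != 1)) {
      stop("interaction_network: observed links must have confidence 1")
    }
    if (any(labels < 0 | labels > 1)) {
      stop("interaction_network: labels must lie in [0,1]")
    }
  }
  structure(list(entity_ids = entity_ids, label_space = space,
                 links = links, labels = labels),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  st <- table(factor(x$links$status, c("observed", "unobserved", "pseudo")))
  cat(sprintf("<interaction_network: %d entities, %d links (%d observed, %d unobserved, %d pseudo), %s C=%d>\n",
              length(x$entity_ids), nrow(x$links), st[["observed"]],
              st[["unobserved"]], st[["pseudo"]],
              x$label_space$type, x$label_space$n_classes))
  invisible(x)
}

parse_label_token <- function(token, space, row) {
  token <- trimws(token)
  C <- space$n_classes
  y <- numeric(C)
  if (space$type == "binary") {
    if (token %in% c("1", space$classes)) y[1L] <- 1
    else if (token %in% c("0", "none")) y[1L] <- 0
    else stop(sprintf("read_interaction_table: unknown label token '%s' at row %d",
                      token, row))
    return(y)
  }
  if (token %in% c("0", "none", "")) return(y)
  parts <- trimws(strsplit(token, ",", fixed = TRUE)[[1L]])
  hit <- match(parts, space$classes)
  if (anyNA(hit)) {
    stop(sprintf("read_interaction_table: unknown label token '%s' at row %d",
                 parts[which(is.na(hit))[1L]], row))
  }
  y[hit] <- 1
  y
}

#' Read an interaction table
#'
#' Parses a tab-separated file with rows `id_a  id_b  label[,label...]` and an
#' optional fourth `status` column (`observed`/`unobserved`; default
#' `observed`). Entity ids are index-mapped in first-appearance order; pairs
#' are canonicalized; a pair listed twice with identical labels is collapsed
#' to one link, while conflicting duplicates are an error.
#'
#' @param path Path to the tab-separated file (no header).
#' @param space A [label_space()] describing how to parse label tokens.
#' @return An [interaction_network()].
#' @export
read_interaction_table <- function(path, space) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(raw) < 3L) stop("read_interaction_table: expected at least 3 tab-separated columns")
  ids <- unique(c(rbind(raw[[1L]], raw[[2L]])))
  n <- nrow(raw)
  i <- match(raw[[1L]], ids); j <- match(raw[[2L]], ids)
  if (any(i == j)) {
    stop(sprintf("read_interaction_table: self-interaction at row %d forbidden",
                 which(i == j)[1L]))
  }
  labels <- t(vapply(seq_len(n), function(r) parse_label_token(raw[[3L]][r], space, r),
                     numeric(space$n_classes)))
  status <- if (ncol(raw) >= 4L) raw[[4L]] else rep("observed", n)
  ii <- pmin(i, j); jj <- pmax(i, j)
  key <- paste(ii, jj)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      lab <- labels[rows, , drop = FALSE]
      if (any(apply(lab, 2L, function(col) length(unique(col)) > 1L)) ||
          length(unique(status[rows])) > 1L) {
        stop(sprintf("read_interaction_table: pair at rows %s listed with conflicting labels",
                     paste(rows, collapse = ", ")))
      }
    }
    keep <- !duplicated(key)
    ii <- ii[keep]; jj <- jj[keep]
    labels <- labels[keep, , drop = FALSE]
    status <- status[keep]
  }
  links <- data.frame(i = ii, j = jj, status = status,
                      confidence = ifelse(status == "observed", 1, 0),
                      stringsAsFactors = FALSE)
  interaction_network(ids, space, links, labels)
}

#' Write an interaction network to the tab-separated table format
#'
#' Emits `id_a  id_b  label  status` rows (the inverse of
#' [read_interaction_table()]); pseudo links are written with their `pseudo`
#' status so augmented networks can be serialized.
#'
#' @param network An [interaction_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(network, path) {
  sp <- network$label_space
  tok <- apply(network$labels, 1L, function(y) {
    if (sp$type == "binary") as.character(as.integer(y[1L] >= 0.5))
    else if (!any(y >= 0.5)) "none"
    else paste(sp$classes[y >= 0.5], collapse = ",")
  })
  out <- data.frame(a = network$entity_ids[network$links$i],
                    b = network$entity_ids[network$links$j],
                    label = tok, status = network$links$status)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Adjacency matrix of an interaction network
#'
#' @param network An [interaction_network()].
#' @param include_pseudo Include links with status `pseudo` (default `TRUE`).
#' @return A sparse symmetric 0/1 `Matrix` with zero diagonal.
#' @export
network_adjacency <- function(network, include_pseudo = TRUE) {
  N <- length(network$entity_ids)
  keep <- network$links$status == "observed" |
    (include_pseudo & network$links$status == "pseudo")
  i <- network$links$i[keep]; j <- network$links$j[keep]
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(N, N), use.last.ij = TRUE)
}
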
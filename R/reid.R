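#' Create a labelled embedding gallery
#'
#' A gallery holds appearance embeddings (fixed-dimension real vectors,
#' conventionally 128-dimensional) labelled with person identities. New
#' detections are re-identified by Euclidean nearest neighbour over the
#' individual gallery entries: the query takes the label of the single
#' closest entry (per-entry minimum, not a per-identity average), so one
#' labelled occurrence of a person suffices and additional entries — for
#' example after a wardrobe change — only improve matching.
#'
#' @param embeddings numeric matrix, one row per entry.
#' @param labels character vector of identity labels, one per row.
#' @return An object of class `reid_gallery`.
#' @export
reid_gallery <- function(embeddings = matrix(numeric(), 0L, 0L),
                         labels = character()) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != length(labels))
    stop_input("one label per gallery entry required")
  if (length(labels) > 0L && any(!nzchar(labels) | is.na(labels)))
    stop_input("gallery labels must be non-empty strings")
  if (length(embeddings) > 0L && any(!is.finite(embeddings)))
    stop_input("gallery embeddings must be finite")
  structure(list(embeddings = embeddings, labels = as.character(labels)),
            class = "reid_gallery")
}

#' Euclidean distance between two embeddings
#'
#' @param a,b numeric vectors of equal length.
#' @return The L2 norm of `a - b`.
#' @export
embedding_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_input("embedding dimensionality mismatch: ", length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}

#' Assign an identity to a query embedding
#'
#' Returns the label of the gallery entry at minimal Euclidean distance
#' from the query. When the minimum exceeds `max_distance` the query is
#' `"unknown"` (by default the threshold is unlimited: every detection
#' receives an identity). Exact distance ties are broken toward the
#' lexicographically smallest label, then the earliest entry, so
#' assignment does not depend on gallery insertion order.
#'
#' @param query numeric embedding vector.
#' @param gallery a [reid_gallery].
#' @param max_distance rejection threshold (default `Inf`).
#' @return Identity label, or `"unknown"`.
#' @export
assign_identity <- function(query, gallery, max_distance = Inf) {
  stopifnot(inherits(gallery, "reid_gallery"))
  if (length(gallery$labels) == 0L)
    stop_config("cannot assign identities against an empty gallery")
  if (ncol(gallery$embeddings) != length(query))
    stop_input("embedding dimensionality mismatch: query ", length(query),
               " vs gallery ", ncol(gallery$embeddings))
  d <- sqrt(colSums((t(gallery$embeddings) - query)^2))
  o <- order(d, gallery$labels, seq_along(d))
  best <- o[1L]
  if (d[best] > max_distance) "unknown" else gallery$labels[best]
}

#' Append a labelled embedding to a gallery
#'
#' Existing entries are untouched; adding entries can only shrink the
#' minimal distance for any query. A previously unseen label introduces a
#' new identity.
#'
#' @param gallery a [reid_gallery].
#' @param embedding numeric embedding vector.
#' @param label non-empty identity label.
#' @return The grown [reid_gallery].
#' @export
update_gallery <- function(gallery, embedding, label) {
  stopifnot(inherits(gallery, "reid_gallery"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label) || is.na(label))
    stop_input("label must be a single non-empty string")
  if (nrow(gallery$embeddings) > 0L &&
      ncol(gallery$embeddings) != length(embedding))
    stop_input("embedding dimensionality mismatch: ", length(embedding),
               " vs gallery ", ncol(gallery$embeddings))
  emb <- if (nrow(gallery$embeddings) == 0L) matrix(embedding, nrow = 1L)
         else rbind(gallery$embeddings, embedding, deparse.level = 0L)
  reid_gallery(emb, c(gallery$labels, label))
}

#' Re-identify every detection in an embedding table
#'
#' Batch [assign_identity()] over a per-frame embedding table (one row per
#' detected person per frame, columns `frame`, `person`, `e0..e<d-1>`).
#'
#' @param embeddings embedding data.frame (see [read_embeddings()]).
#' @param gallery a [reid_gallery].
#' @param max_distance rejection threshold (default `Inf`).
#' @return data.frame `frame`, `person`, `identity`.
#' @export
assign_identities <- function(embeddings, gallery, max_distance = Inf) {
  stopifnot(inherits(gallery, "reid_gallery"))
  if (length(gallery$labels) == 0L)
    stop_config("cannot assign identities against an empty gallery")
  ecols <- grep("^e[0-9]+$", names(embeddings), value = TRUE)
  Q <- as.matrix(embeddings[, ecols, drop = FALSE])
  G <- gallery$embeddings
  if (ncol(Q) != ncol(G))
    stop_input("embedding dimensionality mismatch: ", ncol(Q),
               " vs gallery ", ncol(G))
  # squared-distance matrix queries x gallery via the expansion
  # |q - g|^2 = |q|^2 + |g|^2 - 2 q.g, clamped at 0 for rounding
  D2 <- pmax(outer(rowSums(Q^2), rowSums(G^2), "+") - 2 * Q %*% t(G), 0)
  ord <- order(gallery$labels, seq_along(gallery$labels))
  D2 <- D2[, ord, drop = FALSE]
  labs <- gallery$labels[ord]
  best <- apply(D2, 1L, which.min)  # first minimum = smallest label, earliest
  identity <- labs[best]
  dmin <- sqrt(D2[cbind(seq_len(nrow(Q)), best)])
  identity[dmin > max_distance] <- "unknown"
  data.frame(frame = embeddings$frame, person = embeddings$person,
             identity = identity, stringsAsFactors = FALSE)
}

#' @export
print.reid_gallery <- function(x, ...) {
  cat(sprintf("<reid_gallery> %d entries, %d identities, %d dimensions\n",
              length(x$labels), length(unique(x$labels)),
              ncol(x$embeddings)))
  if (length(x$labels)) print(table(x$labels))
  invisible(x)
}
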
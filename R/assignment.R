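#' Assign a series to a reference cluster by nearest codebook
#'
#' Finds the reference employee whose codebook triple is nearest to the
#' query (in [employee_distance()]) and returns that employee's cluster
#' label. Ties break deterministically to the smaller employee id. This is
#' how new or partial series (e.g. the first half of a follow-up) are
#' mapped onto an existing clustering.
#'
#' @param query Named list of three `codebook`s built with the same
#'   `(m, t)` as the store.
#' @param store A [codebook_store()] with labels.
#' @param alpha Divergence order.
#' @return A list with `cluster` (label of the nearest reference
#'   employee), `nn_id`, and `distance`.
#' @export
assign_to_clusters <- function(query, store, alpha = 0.5) {
  if (length(store$entries) == 0) stopf("reference store is empty")
  qm <- unique(vapply(query, `[[`, integer(1), "m"))
  qt <- unique(vapply(query, `[[`, integer(1), "t"))
  if (!identical(qm, store$m) || !identical(qt, store$t)) {
    stopf("query built with (m = %s, t = %s) but store has (m = %d, t = %d)",
          paste(qm, collapse = "/"), paste(qt, collapse = "/"),
          store$m, store$t)
  }
  ids <- sort(names(store$entries))
  d <- vapply(ids, function(id) {
    employee_distance(query, store$entries[[id]], alpha)
  }, numeric(1))
  best <- which.min(d) # first minimum: smaller id wins on ties
  list(cluster = unname(store$labels[ids[best]]),
       nn_id = ids[best], distance = unname(d[best]))
}

#' Assign many series at once
#'
#' @param queries Named list of codebook triples.
#' @inheritParams assign_to_clusters
#' @return A data frame with one row per query: `employee_id`, `cluster`,
#'   `nn_id`, `distance`.
#' @export
assign_many <- function(queries, store, alpha = 0.5) {
  rows <- lapply(names(queries), function(id) {
    a <- assign_to_clusters(queries[[id]], store, alpha)
    data.frame(employee_id = id, cluster = a$cluster, nn_id = a$nn_id,
               distance = a$distance, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Self-assignment rate of half-series queries
#'
#' Fraction of employees whose half-series codebooks are nearest (among
#' all reference employees) to their own full-series codebooks — a
#' stability diagnostic for the past/future split.
#'
#' @param store Reference [codebook_store()].
#' @param half_codebooks Named list of codebook triples for the same
#'   employee ids as the store.
#' @param alpha Divergence order.
#' @return Fraction in `[0, 1]`.
#' @export
self_assignment_rate <- function(store, half_codebooks, alpha = 0.5) {
  if (!setequal(names(half_codebooks), names(store$entries))) {
    stopf("store and queries must cover the same employees")
  }
  hits <- vapply(names(half_codebooks), function(id) {
    assign_to_clusters(half_codebooks[[id]], store, alpha)$nn_id == id
  }, logical(1))
  mean(hits)
}
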
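#' Build the default parcellation table
#'
#' The analysis operates on parcellated time series: 400 cortical parcels
#' labelled with one of the seven canonical resting-state networks
#' (visual, somatomotor, dorsal attention, salience/ventral attention,
#' limbic, control/central executive, default mode) plus 54 subcortical
#' parcels. Network membership drives both the construction of synthetic
#' state patterns and the network labelling of fitted CAP centroids, so the
#' table is the single source of truth for parcel order.
#'
#' @param n_cortical number of cortical parcels (default 400).
#' @param n_subcortical number of subcortical parcels (default 54).
#' @return a data.frame with columns `parcel_id`, `name`, `network`,
#'   `source`, one row per parcel, cortical first.
#' @export
#' @examples
#' pt <- build_parcel_table()
#' table(pt$network)
build_parcel_table <- function(n_cortical = 400, n_subcortical = 54) {
  stopifnot(n_cortical >= 7, n_subcortical >= 0)
  networks <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
  # spread cortical parcels as evenly as possible across the 7 networks,
  # keeping parcels of one network contiguous (as in atlas orderings)
  base_n <- n_cortical %/% 7
  extra <- n_cortical %% 7
  sizes <- rep(base_n, 7) + c(rep(1, extra), rep(0, 7 - extra))
  net <- rep(networks, times = sizes)
  cort <- data.frame(
    parcel_id = seq_len(n_cortical),
    name = paste0("ctx_", net, "_", unlist(lapply(sizes, seq_len))),
    network = net,
    source = "cortical",
    stringsAsFactors = FALSE
  )
  if (n_subcortical > 0) {
    sub <- data.frame(
      parcel_id = n_cortical + seq_len(n_subcortical),
      name = paste0("subctx_", seq_len(n_subcortical)),
      network = "subcortical",
      source = "subcortical",
      stringsAsFactors = FALSE
    )
    cort <- rbind(cort, sub)
  }
  class(cort) <- c("parcel_table", "data.frame")
  cort
}

validate_parcel_table <- function(pt) {
  need_fields(pt, c("parcel_id", "name", "network", "source"), "parcel table")
  if (anyDuplicated(pt$parcel_id)) stop("parcel table has duplicate parcel ids")
  invisible(pt)
}

# Binary membership indicators over parcels, one column per network.
network_indicators <- function(pt, networks = NULL) {
  validate_parcel_table(pt)
  if (is.null(networks)) networks <- setdiff(unique(pt$network), character(0))
  ind <- vapply(networks, function(nw) as.numeric(pt$network == nw), numeric(nrow(pt)))
  empty <- colSums(ind) == 0
  if (any(empty)) stop(sprintf("network(s) with zero parcels: %s",
                               paste(networks[empty], collapse = ", ")))
  colnames(ind) <- networks
  ind
}
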
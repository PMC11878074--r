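#' First-order-neighbour (FON) graph around biomarker taxa
#'
#' Induces the subgraph on the biomarker taxa and all of their first-order
#' neighbours, and assigns each node a role: biomarkers keep their class
#' (`biomarker_inc` / `biomarker_dec`, even when adjacent to the other
#' class); non-biomarker neighbours adjacent to biomarkers of both classes
#' are `shared_nn`; the rest are `nn_inc` or `nn_dec` after the class they
#' neighbour. Cluster I is the increased biomarkers with their neighbours,
#' cluster II the decreased ones with theirs, and the shared neighbours form
#' the bridge cluster between them.
#'
#' @param net An `sna_network` (typically built per cohort; the FON graphs
#'   of the two cohorts are compared side by side).
#' @param increased,decreased Disjoint character vectors of biomarker taxa,
#'   subsets of `net$taxa`.
#' @param cohort_tag Optional `"A"`/`"B"` tag recording which cohort's
#'   network was used.
#' @return An `sna_fon`: list with `nodes` (tibble `taxon`, `role`),
#'   `edges` (tibble `taxon_i`, `taxon_j`, `weight`, `sign` of the induced
#'   subgraph), and `cohort_tag`.
#' @export
extract_fon <- function(net, increased, decreased, cohort_tag = NA) {
  stopifnot(inherits(net, "sna_network"))
  increased <- as.character(increased)
  decreased <- as.character(decreased)
  if (length(intersect(increased, decreased))) {
    abort("biomarker sets must be disjoint")
  }
  unknown <- setdiff(c(increased, decreased), net$taxa)
  if (length(unknown)) {
    abort(paste0("biomarkers not in network: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!length(increased) && !length(decreased)) {
    warn("empty biomarker sets: FON graph is empty")
    return(structure(list(nodes = tibble(taxon = character(),
                                         role = character()),
                          edges = tibble(taxon_i = character(),
                                         taxon_j = character(),
                                         weight = double(),
                                         sign = integer()),
                          cohort_tag = cohort_tag),
                     class = "sna_fon"))
  }
  A <- net$A
  bio <- c(increased, decreased)
  bidx <- match(bio, net$taxa)
  nb <- which(colSums(A[bidx, , drop = FALSE]) > 0)
  keep <- sort(union(bidx, nb))
  taxa <- net$taxa[keep]

  adj_inc <- colSums(A[match(increased, net$taxa), keep, drop = FALSE]) > 0
  adj_dec <- colSums(A[match(decreased, net$taxa), keep, drop = FALSE]) > 0
  role <- dplyr::case_when(
    taxa %in% increased ~ "biomarker_inc",
    taxa %in% decreased ~ "biomarker_dec",
    adj_inc & adj_dec ~ "shared_nn",
    adj_inc ~ "nn_inc",
    adj_dec ~ "nn_dec"
  )

  sub <- net
  sub$taxa <- taxa
  sub$W <- net$W[keep, keep, drop = FALSE]
  sub$sign <- net$sign[keep, keep, drop = FALSE]
  sub$A <- net$A[keep, keep, drop = FALSE]
  structure(list(nodes = tibble(taxon = taxa, role = role),
                 edges = tidy(sub),
                 cohort_tag = cohort_tag),
            class = "sna_fon")
}

#' @export
print.sna_fon <- function(x, ...) {
  cat("<sna_fon> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  print(table(x$nodes$role))
  invisible(x)
}

#' @method tidy sna_fon
#' @export
tidy.sna_fon <- function(x, ...) {
  x$edges |>
    left_join(x$nodes, by = c(taxon_i = "taxon")) |>
    dplyr::rename(role_i = "role") |>
    left_join(x$nodes, by = c(taxon_j = "taxon")) |>
    dplyr::rename(role_j = "role")
}

# P/N over the FON edges linking roles in `from` to roles in `to`
# (between-cluster edges only; edges internal to a role set are not counted
# unless the same role appears in both sets).
fon_cell_pn <- function(fon, from, to) {
  e <- tidy(fon)
  sel <- (e$role_i %in% from & e$role_j %in% to) |
         (e$role_i %in% to & e$role_j %in% from)
  vals <- e$sign[sel]
  n_pos <- sum(vals > 0)
  n_neg <- sum(vals < 0)
  out <- if (n_pos + n_neg == 0L) NaN else n_pos / n_neg
  structure(out, n_pos = n_pos, n_neg = n_neg)
}

#' P/N ratios between the critical clusters of a FON graph
#'
#' The four positive/negative edge-count ratios reported per cohort:
#' cluster I biomarkers to their own neighbours, cluster I to the shared
#' neighbours, cluster II to its neighbours, and cluster II to the shared
#' neighbours. Only between-cluster edges are counted. Positive-only cells
#' format as `"-"`; empty cells as `"NA"`.
#'
#' @param fon An `sna_fon`.
#' @return A tibble with columns `cluster_pair`, `n_pos`, `n_neg`, `pn`
#'   (numeric; `Inf` = positive only, `NaN` = no edges), `cell` (formatted).
#' @export
fon_pn_table <- function(fon) {
  stopifnot(inherits(fon, "sna_fon"))
  cells <- list(
    cluster_I_vs_nn = list("biomarker_inc", "nn_inc"),
    cluster_I_vs_shared_nn = list("biomarker_inc", "shared_nn"),
    cluster_II_vs_nn = list("biomarker_dec", "nn_dec"),
    cluster_II_vs_shared_nn = list("biomarker_dec", "shared_nn")
  )
  purrr::imap_dfr(cells, function(pair, nm) {
    r <- fon_cell_pn(fon, pair[[1]], pair[[2]])
    tibble(cluster_pair = nm,
           n_pos = attr(r, "n_pos"), n_neg = attr(r, "n_neg"),
           pn = as.numeric(r), cell = format_pn(r))
  })
}

#' Mine all-positive biomarker subgroups ("allies")
#'
#' Finds cooperative biomarker sub-communities: the connected components of
#' the subgraph induced on the biomarker taxa restricted to positive edges.
#' Components of at least `min_size` taxa are returned, largest first (ties
#' broken by mean edge weight); each carries its internal positive edge
#' list and a flag for whether every pair is directly connected.
#'
#' @param net An `sna_network`.
#' @param biomarker_taxa Character vector of biomarker taxa (subset of
#'   `net$taxa`).
#' @param min_size Minimum component size to report (default 3).
#' @return A list of subgroups, each a list with `taxa`, `edges` (tibble),
#'   `size`, `mean_weight`, `complete` (all-pairs-connected flag).
#' @export
mine_subgroups <- function(net, biomarker_taxa, min_size = 3) {
  stopifnot(inherits(net, "sna_network"))
  biomarker_taxa <- as.character(biomarker_taxa)
  unknown <- setdiff(biomarker_taxa, net$taxa)
  if (length(unknown)) {
    abort(paste0("biomarkers not in network: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!length(biomarker_taxa)) return(list())
  idx <- match(biomarker_taxa, net$taxa)
  pos <- (net$sign[idx, idx, drop = FALSE] > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(pos, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$name <- biomarker_taxa
  comp <- igraph::components(g)
  groups <- split(biomarker_taxa, comp$membership)
  groups <- Filter(function(gr) length(gr) >= min_size, groups)
  out <- lapply(groups, function(gr) {
    gi <- match(gr, net$taxa)
    sub <- net$sign[gi, gi, drop = FALSE] > 0
    ut <- which(upper.tri(sub) & sub, arr.ind = TRUE)
    edges <- tibble(taxon_i = gr[ut[, 1L]], taxon_j = gr[ut[, 2L]],
                    weight = net$W[cbind(gi[ut[, 1L]], gi[ut[, 2L]])])
    list(taxa = gr, edges = edges, size = length(gr),
         mean_weight = if (nrow(edges)) mean(edges$weight) else NA_real_,
         complete = nrow(edges) == choose(length(gr), 2))
  })
  ord <- order(-vapply(out, `[[`, 0, "size"),
               -vapply(out, function(g) g$mean_weight %||% 0, 0))
  unname(out[ord])
}

#' Write a FON graph as GraphML
#'
#' Nodes carry a `role` attribute and edges `weight` and `sign`, so the
#' graph renders with the usual cluster styling in standard viewers.
#'
#' @param fon An `sna_fon`.
#' @param path Output path.
#' @return Invisibly, `fon`.
#' @export
write_fon_graphml <- function(fon, path) {
  stopifnot(inherits(fon, "sna_fon"))
  g <- igraph::graph_from_data_frame(
    as.data.frame(fon$edges), directed = FALSE,
    vertices = as.data.frame(fon$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(fon)
}
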
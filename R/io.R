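#' Write a co-occurrence network to disk
#'
#' Writes either a GraphML file (openable in standard graph viewers; edge
#' attributes `weight` and `sign`, node attribute `name`) or a plain
#' tab-separated edge list with columns `taxon_i`, `taxon_j`, `weight`,
#' `sign`, each undirected edge once with `taxon_i` before `taxon_j` in taxon
#' order. The edge-list format carries the full taxon list in a `# taxa:`
#' comment line so isolated nodes round-trip.
#'
#' @param net An `sna_network`.
#' @param path Output path.
#' @param format `"edge_tsv"` (default) or `"graphml"`.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  stopifnot(inherits(net, "sna_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(net))
  }
  edges <- tidy(net)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# taxa: ", paste(net$taxa, collapse = "\t")), con)
  writeLines(paste0("# estimator: ", net$estimator_tag), con)
  writeLines("taxon_i\ttaxon_j\tweight\tsign", con)
  if (nrow(edges)) {
    writeLines(sprintf("%s\t%s\t%.17g\t%+d", edges$taxon_i, edges$taxon_j,
                       edges$weight, edges$sign), con)
  }
  invisible(net)
}

#' Read a network from an edge-list TSV written by [write_network()]
#'
#' @param path Path to the edge-list file.
#' @return An `sna_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  taxa_line <- grep("^# taxa: ", lines, value = TRUE)
  if (!length(taxa_line)) abort("edge file lacks '# taxa:' header line")
  taxa <- strsplit(sub("^# taxa: ", "", taxa_line[1L]), "\t")[[1L]]
  est_line <- grep("^# estimator: ", lines, value = TRUE)
  est <- if (length(est_line)) sub("^# estimator: ", "", est_line[1L]) else "unknown"
  body <- lines[!grepl("^#", lines)]
  n <- length(taxa)
  W <- diag(n)
  sgn <- matrix(0, n, n)
  A <- matrix(0, n, n)
  dimnames(W) <- dimnames(sgn) <- dimnames(A) <- list(taxa, taxa)
  if (length(body) > 1L) {
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    i <- match(df$taxon_i, taxa)
    j <- match(df$taxon_j, taxa)
    if (anyNA(i) || anyNA(j)) abort("edge file references taxa not in header")
    W[cbind(i, j)] <- W[cbind(j, i)] <- df$weight
    sgn[cbind(i, j)] <- sgn[cbind(j, i)] <- df$sign
    A[cbind(i, j)] <- A[cbind(j, i)] <- 1
  }
  structure(list(taxa = taxa, W = W, sign = sgn, A = A, estimator_tag = est),
            class = "sna_network")
}

# sna_network -> igraph, with signed weights as edge attributes.
as_igraph <- function(net, roles = NULL) {
  edges <- tidy(net)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = net$taxa, stringsAsFactors = FALSE))
  if (!is.null(roles)) {
    igraph::V(g)$role <- unname(roles[igraph::V(g)$name])
  }
  g
}

#' Write a stiffness profile as a TSV table
#'
#' One row per taxon with columns `taxon`, `f`, `d`, `s`, `I`, `S`, followed
#' by a summary footer row giving `mean [min, max]` per column. Undefined
#' entries serialize as `NA` and are excluded from the summary statistics.
#'
#' @param profile An `sna_profile` from [compute_profile()].
#' @param path Output path.
#' @param digits Significant digits for the summary cells.
#' @return Invisibly, `profile`.
#' @export
write_profile <- function(profile, path, digits = 4) {
  stopifnot(inherits(profile, "sna_profile"))
  cols <- c(f = "force", d = "displacement", s = "stiffness_scale",
            I = "impact", S = "stability")
  df <- as.data.frame(profile)[, c("taxon", unname(cols))]
  names(df) <- c("taxon", names(cols))
  summary_cells <- vapply(names(cols), function(cc) {
    v <- df[[cc]][!is.na(df[[cc]])]
    if (!length(v)) return("NA")
    fmt <- function(z) as.character(signif(z, digits))
    paste0(fmt(mean(v)), " [", fmt(min(v)), ", ", fmt(max(v)), "]")
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    vals <- vapply(names(cols), function(cc) {
      v <- df[[cc]][i]
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
    writeLines(paste(c(df$taxon[i], vals), collapse = "\t"), con)
  }
  writeLines(paste(c("mean [min, max]", summary_cells), collapse = "\t"), con)
  invisible(profile)
}
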
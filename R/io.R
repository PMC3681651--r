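#' Read and write spike rasters as delimited text
#'
#' Tab-delimited layout: comment header lines \code{# unit <tab> region}
#' per unit (in row order), then the binary matrix, units in rows, one
#' column per 1-ms bin, no column header.
#'
#' @param raster a \linkS4class{SpikeRaster}
#' @param path file path
#' @return \code{writeRaster}: invisibly, the path; \code{readRaster}: a
#'   \linkS4class{SpikeRaster}
#' @export
writeRaster <- function(raster, path) {
  stopifnot(is(raster, "SpikeRaster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", raster@units, "\t", raster@regions), con)
  write.table(spikeMatrix(raster), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- do.call(rbind, strsplit(sub("^# ", "", lines[hdr]), "\t"))
  m <- as.matrix(read.table(text = lines[-hdr], sep = "\t"))
  dimnames(m) <- NULL
  SpikeRaster(m, units = meta[, 1], regions = meta[, 2])
}

#' Read and write LFP channel sets as delimited text
#'
#' Tab-delimited, one column per channel. Header comments carry the
#' sampling rate and per-channel regions; the first non-comment row holds
#' channel ids.
#'
#' @param lfp an \linkS4class{LFPSet}
#' @param path file path
#' @return \code{writeLfp}: invisibly, the path; \code{readLfp}: an
#'   \linkS4class{LFPSet}
#' @export
writeLfp <- function(lfp, path) {
  stopifnot(is(lfp, "LFPSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# rate\t", lfp@samplingRate),
               paste0("# regions\t", paste(lfp@regions, collapse = "\t"))),
             con)
  write.table(signalMatrix(lfp), con, sep = "\t", row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLfp
#' @export
readLfp <- function(path) {
  lines <- readLines(path)
  rate <- as.numeric(strsplit(lines[grep("^# rate", lines)], "\t")[[1]][2])
  regions <- strsplit(lines[grep("^# regions", lines)], "\t")[[1]][-1]
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, sep = "\t", header = TRUE)
  LFPSet(as.matrix(df), samplingRate = rate, channels = colnames(df),
         regions = regions)
}

#' Write a weighted adjacency matrix as delimited text
#'
#' Square matrix with a header row (and column) of unit ids.
#'
#' @param adj a \linkS4class{FunctionalAdjacency}
#' @param path file path
#' @return invisibly, the path
#' @export
writeAdjacency <- function(adj, path) {
  stopifnot(is(adj, "FunctionalAdjacency"))
  write.table(weightMatrix(adj), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Read a weighted adjacency matrix written by \code{writeAdjacency}
#'
#' @param path file path
#' @param method similarity method label to record
#' @return a \linkS4class{FunctionalAdjacency}
#' @export
readAdjacency <- function(path, method = "ncs") {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  units <- rownames(m)
  dimnames(m) <- NULL
  diag(m) <- 0
  new("FunctionalAdjacency", weights = m, units = units,
      regions = rep("R1", nrow(m)), windowId = 1L, method = method)
}

#' Export a functional graph
#'
#' GraphML via igraph, or a plain whitespace edge list of unit ids.
#'
#' @param fg a \linkS4class{FunctionalGraph}
#' @param path file path
#' @param format "graphml" or "edgelist"
#' @return invisibly, the path
#' @export
writeGraph <- function(fg, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- asIgraph(fg)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Dump an assembly model as GraphML files
#'
#' Writes one GraphML file per member assembly (\code{assembly_<k>.graphml}
#' under \code{dir}), vertices annotated with their pool node id and
#' intra-window firing offset.
#'
#' @param model an \linkS4class{AssemblyModel}
#' @param dir output directory (created if missing)
#' @return invisibly, the vector of files written
#' @export
writeModel <- function(model, dir) {
  stopifnot(is(model, "AssemblyModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(model@assemblies), function(k) {
    a <- model@assemblies[[k]]
    g <- a$graph
    g <- igraph::set_vertex_attr(g, "poolNode", value = a$nodes)
    g <- igraph::set_vertex_attr(g, "offset", value = a$offset)
    p <- file.path(dir, sprintf("assembly_%d.graphml", k))
    igraph::write_graph(g, p, format = "graphml")
    p
  }, character(1))
  invisible(paths)
}

#' Write a small-world report table
#'
#' One row per graph in the layout of the published report tables: nodes,
#' edges, win, theta, C, C_latt, C_rand, L, L_rand, S, omega.
#'
#' @param report data.frame as returned in \code{runSpikePipeline()$report}
#' @param path file path
#' @return invisibly, the path
#' @export
writeReport <- function(report, path) {
  cols <- c("nodes", "edges", "win", "theta", "C", "C_latt", "C_rand",
            "L", "L_rand", "S", "omega")
  keep <- intersect(cols, colnames(report))
  write.table(report[, keep, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
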
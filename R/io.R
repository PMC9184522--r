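#' Read a clustered expression dataset
#'
#' Two layouts are supported. A directory containing Matrix Market triplet
#' counts (\code{matrix.mtx}, 1-based indices per the standard) with
#' \code{genes.tsv}, \code{barcodes.tsv} and \code{clusters.tsv} (columns
#' cell_id, cluster; no headers except clusters.tsv which has none either);
#' or a dense CSV whose first row holds the cluster label of each cell and
#' the remaining rows the gene counts. Duplicate gene symbols are collapsed
#' by summing with a warning; every cell must carry a cluster label.
#'
#' @param path directory or CSV file
#' @return a \code{SingleCellExperiment} with \code{counts},
#'   \code{logcounts} and a \code{cluster} column
#' @export
readExpression <- function(path) {
    if (dir.exists(path)) {
        m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
        genes <- readLines(file.path(path, "genes.tsv"))
        cells <- readLines(file.path(path, "barcodes.tsv"))
        if (nrow(m) != length(genes) || ncol(m) != length(cells))
            stop("dimension mismatch between matrix and gene/barcode tables")
        cltab <- read.delim(file.path(path, "clusters.tsv"), header = FALSE,
                            col.names = c("cell_id", "cluster"),
                            stringsAsFactors = FALSE)
        cl <- cltab$cluster[match(cells, cltab$cell_id)]
        if (anyNA(cl))
            stop("cells without a cluster label: ",
                 paste(head(cells[is.na(cl)], 5), collapse = ", "))
        dimnames(m) <- list(genes, cells)
    } else {
        raw <- read.csv(path, row.names = 1, check.names = FALSE,
                        stringsAsFactors = FALSE)
        if (rownames(raw)[1] != "cluster")
            stop("dense CSV must carry a 'cluster' row first")
        cl <- as.character(unlist(raw[1, ]))
        m <- as.matrix(raw[-1, , drop = FALSE])
        storage.mode(m) <- "double"
        if (anyNA(cl) | any(!nzchar(cl)))
            stop("cells without a cluster label: ",
                 paste(head(colnames(m)[is.na(cl) | !nzchar(cl)], 5),
                       collapse = ", "))
    }
    if (any(m < 0)) stop("negative counts")
    if (anyDuplicated(rownames(m))) {
        warning("duplicate gene symbols collapsed by sum")
        m <- rowsum(m, rownames(m))
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m, logcounts = normalizeCounts(m)),
        colData = S4Vectors::DataFrame(cluster = cl,
                                       row.names = colnames(m)))
}

#' Write a clustered expression dataset
#'
#' Inverse of [readExpression()]: Matrix Market triplet plus gene, barcode
#' and cluster tables into a directory, or a dense CSV with a leading
#' cluster row.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts} and a
#'   \code{cluster} column
#' @param path output directory (created) or a path ending in \code{.csv}
#' @return invisibly, \code{path}
#' @export
writeExpression <- function(sce, path) {
    m <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
    cl <- as.character(SummarizedExperiment::colData(sce)$cluster)
    if (grepl("\\.csv$", path)) {
        out <- rbind(cluster = cl, m)
        utils::write.csv(out, path, quote = FALSE)
    } else {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                        file.path(path, "matrix.mtx"))
        writeLines(rownames(m), file.path(path, "genes.tsv"))
        writeLines(colnames(m), file.path(path, "barcodes.tsv"))
        write.table(data.frame(colnames(m), cl),
                    file.path(path, "clusters.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Write a scored-interaction table with a reproducibility header
#'
#' Long-format TSV preceded by comment lines recording the package version,
#' seed and a hash of the configuration.
#'
#' @param scored long-format scored table
#' @param path output TSV path
#' @param seed seed to record
#' @param config a [methodConfig()] (hashed into the header)
#' @return invisibly, \code{path}
#' @export
writeScores <- function(scored, path, seed = NA, config = NULL) {
    hash <- if (is.null(config)) NA_character_ else
        sprintf("%08x", sum(utf8ToInt(paste(
            names(config), unlist(config), collapse = ";")) *
            seq_along(utf8ToInt(paste(names(config), unlist(config),
                                      collapse = ";")))) %% 4294967291)
    con <- file(path, "w")
    writeLines(c(paste0("# CCCbench version ",
                        as.character(utils::packageVersion("CCCbench"))),
                 paste0("# seed ", seed),
                 paste0("# config_hash ", hash)), con)
    write.table(scored, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    invisible(path)
}

#' Read a scored-interaction table written by [writeScores()]
#' @param path TSV path
#' @return long-format \code{data.frame}
#' @export
readScores <- function(path)
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
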
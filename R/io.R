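# Reading/writing expression matrices and proportions, cross-platform
# gene-wise rescaling, run configuration, and model bundles.

# format a numeric vector losslessly: integers as plain digits, everything
# else with 17 significant digits so that read-back is bit-identical
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[whole] <- sprintf("%.0f", x[whole])
  out
}

.assertExpression <- function(values, what = "matrix") {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop(sprintf("%s needs gene rownames and sample colnames", what), call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop(sprintf("%s: duplicate gene id(s): %s", what,
                 paste(unique(rownames(values)[duplicated(rownames(values))]),
                       collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop(sprintf("%s: duplicate sample id(s): %s", what,
                 paste(unique(colnames(values)[duplicated(colnames(values))]),
                       collapse = ", ")), call. = FALSE)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("%s: negative value for gene '%s', sample '%s'", what,
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  }
  invisible(values)
}

#' Read an expression matrix
#'
#' Supported dialects: delimited (`tsv`, `csv`; header row of sample ids,
#' first column of gene ids) and MatrixMarket coordinate triplets (`mtx`,
#' with sidecar id lists `<path>.genes.txt` / `<path>.samples.txt`, one id
#' per line; implicit zeros are filled in). Values must be non-negative and
#' ids unique.
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; default guessed from the
#'   file extension.
#' @return numeric matrix, genes x samples, with dimnames.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  }
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".genes.txt"))
    samples <- readLines(paste0(path, ".samples.txt"))
    if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
      stop("sidecar id lists do not match matrix dimensions", call. = FALSE)
    }
    dimnames(m) <- list(genes, samples)
    return(.assertExpression(m, path))
  }
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  if (ncol(dt) < 2) stop(sprintf("%s: no sample columns", path), call. = FALSE)
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(dt[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))[1]
    stop(sprintf("%s: non-numeric entry at data line %d", path, bad), call. = FALSE)
  }
  rownames(m) <- genes
  .assertExpression(m, path)
}

#' Write an expression or proportion matrix
#'
#' Delimited output with a `gene` (or arbitrary) id column first; numeric
#' values are printed with enough digits to round-trip bit-identically
#' through [readExpressionMatrix()].
#'
#' @param values numeric matrix with dimnames.
#' @param path output file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param idColumn header of the first column.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(values, path, format = c("tsv", "csv"),
                                  idColumn = "gene") {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  header <- paste(c(idColumn, colnames(values)), collapse = sep)
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], .fmtNum(values[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- gene-wise cross-platform rescaling ------------------------------------

#' Gene-wise rescaling factors between platforms
#'
#' Computes, for every gene shared between the two inputs, the ratio of its
#' mean expression in the training pseudo-bulks to its mean expression in a
#' set of control bulks measured on the target platform. Applying the
#' factors to bulks from the target platform equalizes per-gene means with
#' the training data, compensating systematic platform differences. Genes
#' with a zero control mean but positive training mean get factor 1 with a
#' warning (the ratio is undefined; the gene is kept unchanged rather than
#' blown up).
#'
#' @param trainPseudobulks genes x samples matrix (training platform).
#' @param controlBulks genes x samples matrix (target platform controls).
#' @return named numeric vector of positive, finite factors over the shared
#'   genes.
#' @seealso [applyRescale()]
#' @export
computeRescaleFactors <- function(trainPseudobulks, controlBulks) {
  shared <- intersect(rownames(trainPseudobulks), rownames(controlBulks))
  if (length(shared) == 0) stop("no shared genes between inputs", call. = FALSE)
  mt <- rowMeans(trainPseudobulks[shared, , drop = FALSE])
  mc <- rowMeans(controlBulks[shared, , drop = FALSE])
  f <- mt / mc
  undef <- mc == 0
  if (any(undef)) {
    warning(sprintf("%d gene(s) with zero control mean kept at factor 1: %s",
                    sum(undef),
                    paste(utils::head(shared[undef], 5), collapse = ", ")))
    f[undef] <- 1
  }
  f[mt == 0 & mc == 0] <- 1
  names(f) <- shared
  f
}

#' Apply gene-wise rescaling factors
#'
#' Multiplies each gene's row by its factor; genes without a factor are
#' dropped (the factor set defines the usable gene space).
#'
#' @param bulks genes x samples matrix.
#' @param factors named numeric vector from [computeRescaleFactors()].
#' @return rescaled matrix over the genes present in `factors`.
#' @export
applyRescale <- function(bulks, factors) {
  keep <- intersect(names(factors), rownames(bulks))
  if (length(keep) == 0) stop("no factor genes present in bulks", call. = FALSE)
  bulks[keep, , drop = FALSE] * factors[keep]
}

# ---- configuration ---------------------------------------------------------

#' Default run configuration
#'
#' All tunable keys with their defaults: `genes.top_k` (variance-filtered
#' gene count), `bulk.cells_per_bulk`, `bulk.n_train`, `bulk.n_test` and
#' `bulk.test_batches` (training/evaluation design), plus the `train.*`
#' optimizer options of [trainOptions()].
#'
#' @return named list.
#' @export
defaultConfig <- function() {
  list(
    genes.top_k = 5000,
    bulk.cells_per_bulk = 100,
    bulk.n_train = 20000,
    bulk.n_test = 1000,
    bulk.test_batches = 10,
    train.max_iters = 1000,
    train.tol = 1e-6,
    train.constrained_gradient = FALSE,
    train.seed = 1L
  )
}

#' Read a run configuration file
#'
#' A flat YAML (or JSON) key-value document; unknown keys are kept, known
#' keys override the defaults of [defaultConfig()].
#'
#' @param path YAML/JSON file.
#' @return named list.
#' @export
readHideConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

# ---- model bundles ---------------------------------------------------------

.safeName <- function(x, i) sprintf("node%02d_%s", i, gsub("[^A-Za-z0-9]+", "_", x))

#' Save a trained model as a plain-text bundle
#'
#' Writes one directory containing the tree (JSON), the gene index, the
#' per-level consensus references, per-node gene weights and rescaling
#' parameters, and a manifest with the recorded configuration. Gene weights
#' once trained can be reused, so persistence round-trips exactly:
#' [readHideModel()] restores a model giving bit-identical predictions.
#'
#' @param model a [HideModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveHideModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCellTree(model@tree, file.path(dir, "tree.json"))
  writeLines(model@genes, file.path(dir, "genes.txt"))
  for (i in seq_along(model@levels)) {
    writeExpressionMatrix(model@references[[i]],
                          file.path(dir, sprintf("reference_level%02d.tsv", i)))
  }
  writeNodePart <- function(prefix, types, weights, rescale) {
    writeLines(paste(names(weights), .fmtNum(weights), sep = "\t"),
               file.path(dir, paste0(prefix, "_weights.tsv")))
    writeLines(c("type\ttheta\tdelta",
                 paste(types, .fmtNum(rescale$theta), .fmtNum(rescale$delta),
                       sep = "\t")),
               file.path(dir, paste0(prefix, "_rescale.tsv")))
  }
  rm0 <- model@rootModel
  writeNodePart("root", rm0$types, rm0$weights, rm0$rescale)
  nodeIndex <- list()
  for (i in seq_along(model@nodeModels)) {
    nm <- model@nodeModels[[i]]
    prefix <- .safeName(nm$node, i)
    writeNodePart(prefix, nm$children, nm$weights, nm$rescale)
    nodeIndex[[i]] <- list(node = nm$node, level = nm$level,
                           children = as.list(nm$children), prefix = prefix)
  }
  manifest <- list(
    package = "hideconv",
    levels = lapply(names(model@levels),
                    function(nm) list(name = nm,
                                      nodes = as.list(model@levels[[nm]]))),
    rootTypes = as.list(model@rootModel$types),
    nodes = nodeIndex,
    config = model@config
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

.readWeights <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

.readRescale <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  list(theta = stats::setNames(as.numeric(dt$theta), dt$type),
       delta = stats::setNames(as.numeric(dt$delta), dt$type))
}

#' Load a model bundle
#'
#' @param dir directory written by [saveHideModel()].
#' @return a [HideModel-class].
#' @export
readHideModel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  tree <- readCellTree(file.path(dir, "tree.json"))
  levels <- lapply(manifest$levels, function(l) unlist(l$nodes, use.names = FALSE))
  names(levels) <- vapply(manifest$levels, function(l) l$name, character(1))
  genes <- readLines(file.path(dir, "genes.txt"))
  references <- lapply(seq_along(levels), function(i) {
    readExpressionMatrix(file.path(dir, sprintf("reference_level%02d.tsv", i)))
  })
  names(references) <- names(levels)
  rootTypes <- unlist(manifest$rootTypes, use.names = FALSE)
  rootModel <- list(types = rootTypes,
                    weights = .readWeights(file.path(dir, "root_weights.tsv")),
                    rescale = .readRescale(file.path(dir, "root_rescale.tsv")))
  nodeModels <- lapply(manifest$nodes, function(n) {
    list(node = n$node, level = n$level,
         children = unlist(n$children, use.names = FALSE),
         weights = .readWeights(file.path(dir, paste0(n$prefix, "_weights.tsv"))),
         rescale = .readRescale(file.path(dir, paste0(n$prefix, "_rescale.tsv"))))
  })
  names(nodeModels) <- vapply(nodeModels, `[[`, character(1), "node")
  cfg <- lapply(manifest$config, function(x) x)
  new("HideModel", tree = tree, levels = levels, genes = genes,
      references = references, rootModel = rootModel,
      nodeModels = nodeModels, config = cfg)
}
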
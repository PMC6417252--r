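# Expression-matrix preprocessing: read, normalize, binarize, aggregate.
#
# The composite dataset behind the WRKY analysis comes from several
# independently processed microarray series; each matrix is normalized on
# its own, thresholded per gene into active/inhibited, and the binarized
# samples are concatenated into one observations-by-nodes dataset for the
# four non-complex nodes (A, B, F, H). Protein-complex columns are created
# as explicitly missing and filled later by the rule-based generator.

#' Read a gene-expression matrix from CSV/TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; all remaining cells must be finite numbers. Missing or
#' non-numeric cells and duplicate gene ids are hard errors (located by
#' gene and sample), never silently coerced.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param dataset optional dataset tag recorded on the result (defaults to
#'   the file name).
#' @return numeric matrix (genes x samples) with a `dataset` attribute.
#' @export
readExpression <- function(path, format = c("auto", "csv", "tsv"),
                           dataset = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE, header = TRUE,
                  colClasses = "character", comment.char = "#")
  if (ncol(raw) < 2) stop("expected a gene-id column plus sample columns")
  genes <- raw[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0)
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, names(raw)[-1]))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    stop("non-numeric or non-finite cell at gene '", rownames(vals)[i[1]],
         "', sample '", colnames(vals)[i[2]], "' (value '",
         raw[i[1], i[2] + 1L], "')")
  }
  attr(vals, "dataset") <- if (is.null(dataset)) basename(path) else dataset
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), basename(path)))
  vals
}

#' Normalize an expression matrix
#'
#' Per-dataset transformation applied before binarization. The published
#' composite was built from individually normalized series without a stated
#' method, so the method is an explicit, recorded choice here.
#'
#' @param m numeric matrix (genes x samples).
#' @param method `"zscore"` (per-gene standardization; default), `"minmax"`
#'   (per-gene scaling to \[0, 1\]) or `"none"`.
#' @return matrix of the same shape with a `normalization` attribute. Under
#'   z-score, a zero-variance gene is centered only, with a warning.
#' @export
normalizeExpression <- function(m, method = c("zscore", "minmax", "none")) {
  method <- match.arg(method)
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("m must be a non-empty numeric matrix")
  out <- m
  if (method == "zscore") {
    for (g in seq_len(nrow(m))) {
      x <- m[g, ]
      s <- sd(x)
      if (is.na(s) || s == 0) {
        warning("gene '", rownames(m)[g],
                "' has zero variance; centered without scaling")
        out[g, ] <- x - mean(x)
      } else out[g, ] <- (x - mean(x)) / s
    }
  } else if (method == "minmax") {
    for (g in seq_len(nrow(m))) {
      x <- m[g, ]
      rng <- range(x)
      out[g, ] <- if (diff(rng) == 0) rep(0, length(x)) else
        (x - rng[1]) / diff(rng)
    }
  }
  attr(out, "dataset") <- attr(m, "dataset")
  attr(out, "normalization") <- method
  out
}

#' Binarize an expression matrix into activation states
#'
#' Per gene, a sample is called activated (1) when its expression is
#' strictly greater than the gene's threshold statistic, else inhibited (0).
#' Ties at the threshold deterministically map to 0. Samples become
#' observations (rows) of the resulting dataset.
#'
#' @param m numeric matrix (genes x samples), typically normalized.
#' @param stat threshold statistic per gene: `"mean"` or `"median"`.
#' @param nodeMap optional named character vector mapping gene ids to
#'   network node ids (gene -> node); genes not in the map are dropped.
#'   Without a map, gene ids are used as column names directly.
#' @return a [BinaryDataset] (observations x nodes/genes), all columns
#'   tagged `"real"`; attributes record the statistic used.
#' @export
binarizeExpression <- function(m, stat = c("mean", "median"), nodeMap = NULL) {
  stat <- match.arg(stat)
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix")
  if (!is.null(nodeMap)) {
    keep <- intersect(rownames(m), names(nodeMap))
    if (length(keep) == 0)
      stop("no gene in the matrix matches the gene-to-node map")
    m <- m[keep, , drop = FALSE]
    rownames(m) <- unname(nodeMap[keep])
    if (anyDuplicated(rownames(m)))
      stop("gene-to-node map sends multiple genes to the same node: ",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  thr <- apply(m, 1L, if (stat == "mean") mean else median)
  bin <- t(ifelse(m > thr, 1L, 0L))  # strict inequality; ties -> 0
  storage.mode(bin) <- "integer"
  ds <- new("BinaryDataset", values = bin,
            provenance = setNames(rep("real", ncol(bin)), colnames(bin)))
  attr(ds@values, "binarization") <- stat
  ds
}

#' Aggregate binarized datasets into one composite
#'
#' Row-wise concatenation over the shared node columns, aligning columns by
#' name (input column order is irrelevant). Protein-complex columns listed
#' in `complexNodes` are created as explicitly missing, ready for
#' [synthesizeAll()]; they are never imputed here.
#'
#' @param datasets list of [BinaryDataset] objects.
#' @param requiredNodes node columns every input must provide
#'   (default the WRKY non-complex nodes A, B, F, H).
#' @param complexNodes node columns to add as missing
#'   (default the WRKY complexes C, D, E, G).
#' @return composite [BinaryDataset] with `sum(nObs)` observations.
#' @export
aggregateBinary <- function(datasets,
                            requiredNodes = c("A", "B", "F", "H"),
                            complexNodes = c("C", "D", "E", "G")) {
  if (length(datasets) == 0) stop("no datasets to aggregate")
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (!is(d, "BinaryDataset")) stop("dataset ", i, " is not a BinaryDataset")
    miss <- setdiff(requiredNodes, colnames(d@values))
    if (length(miss) > 0)
      stop("dataset ", i, " is missing required node column(s): ",
           paste(miss, collapse = ", "))
  }
  blocks <- lapply(datasets, function(d)
    d@values[, requiredNodes, drop = FALSE])
  obs <- do.call(rbind, blocks)
  full <- cbind(obs, matrix(NA_integer_, nrow = nrow(obs),
                            ncol = length(complexNodes),
                            dimnames = list(NULL, complexNodes)))
  full <- full[, sort(colnames(full)), drop = FALSE]
  prov <- setNames(ifelse(colnames(full) %in% complexNodes,
                          "missing", "real"), colnames(full))
  new("BinaryDataset", values = full, provenance = prov)
}
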
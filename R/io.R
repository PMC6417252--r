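# Plain-text serialization: network config, binary datasets, parameters.

#' Write / read a network structure as YAML
#'
#' The config lists each node with its display label, parent ids and
#' complex flag, so alternative networks (or relabeled WRKY variants) can
#' be defined without code.
#'
#' @param net a [BayesNetwork].
#' @param path file path.
#' @return `writeNetworkConfig` returns `path` invisibly;
#'   `readNetworkConfig` returns a [BayesNetwork].
#' @export
writeNetworkConfig <- function(net, path) {
  stopifnot(is(net, "BayesNetwork"))
  cfg <- list(nodes = lapply(setNames(net@nodes, net@nodes), function(nd)
    list(label = unname(net@labels[[nd]]),
         parents = as.list(net@parents[[nd]]),
         complex = unname(net@isComplex[[nd]]))))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$nodes)) stop("network config must have a 'nodes' map")
  ids <- names(cfg$nodes)
  makeNetwork(
    parents = lapply(cfg$nodes, function(x) unlist(x$parents) %||% character(0)),
    labels = setNames(vapply(cfg$nodes, function(x)
      x$label %||% "", character(1)), ids),
    isComplex = setNames(vapply(cfg$nodes, function(x)
      isTRUE(x$complex), logical(1)), ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a BinaryDataset as CSV
#'
#' Plain CSV with one row per observation; column provenance is preserved
#' in a `# provenance:` header comment.
#'
#' @param data a [BinaryDataset].
#' @param path file path.
#' @return `writeBinaryDataset` returns `path` invisibly;
#'   `readBinaryDataset` returns a [BinaryDataset].
#' @export
writeBinaryDataset <- function(data, path) {
  stopifnot(is(data, "BinaryDataset"))
  prov <- provenance(data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ",
                    paste(names(prov), prov, sep = "=", collapse = ",")), con)
  write.csv(as.data.frame(data@values), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBinaryDataset
#' @export
readBinaryDataset <- function(path) {
  header <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  v <- as.matrix(df)
  storage.mode(v) <- "integer"
  prov <- setNames(rep("real", ncol(v)), colnames(v))
  if (grepl("^# provenance:", header)) {
    pairs <- strsplit(strsplit(sub("^# provenance: *", "", header),
                               ",")[[1]], "=")
    for (p in pairs) prov[p[1]] <- p[2]
  }
  prov[colnames(v)[colSums(is.na(v)) == nrow(v)]] <- "missing"
  new("BinaryDataset", values = v, provenance = prov[colnames(v)])
}

#' Write a parameter comparison table as CSV
#'
#' One row per local probability, one column per estimation method.
#'
#' @param comparison data.frame from [compareEstimates()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeParameterTable <- function(comparison, path) {
  write.csv(comparison, path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter set from a CSV file
#'
#' Expects columns `node`, `config`, `theta`; used e.g. to inject an
#' externally supplied parameter table into the ranking stage.
#'
#' @param path file path.
#' @param net the [BayesNetwork] the parameters belong to.
#' @return a [ParameterSet].
#' @export
readParameterSet <- function(path, net) {
  df <- read.csv(path, colClasses = c(node = "character",
                                      config = "character"))
  if (!all(c("node", "config", "theta") %in% names(df)))
    stop("parameter file needs columns node, config, theta")
  thetas <- lapply(setNames(net@nodes, net@nodes), function(nd) {
    sub <- df[df$node == nd, ]
    setNames(sub$theta, sub$config)
  })
  makeParameterSet(net, thetas)
}

#' Read a utility table from a config list or YAML file
#'
#' The config carries `scope` (ordered node ids) and `entries`, a list of
#' rows each giving the scope node states plus a `utility` value.
#'
#' @param x a list (already parsed) or a YAML file path.
#' @return a [UtilityTable].
#' @export
readUtilityConfig <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg$scope) || is.null(cfg$entries))
    stop("utility config needs 'scope' and 'entries'")
  scope <- unlist(cfg$scope)
  df <- do.call(rbind, lapply(cfg$entries, function(e)
    as.data.frame(e[c(scope, "utility")])))
  makeUtilityTable(scope, df)
}
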
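# Display rounding used in report tables: 2 decimals, round-half-even
# (base round()), fixed notation.
formatRound2 <- function(x) formatC(round(x, 2), format = "f", digits = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (nrow(tb) == 0L && ncol(tb) == 0L) {
    stop("empty file: ", path, call. = FALSE)
  }
  tb
}

.writeTsv <- function(tb, path) {
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.numericColumn <- function(tb, col, path) {
  x <- suppressWarnings(as.numeric(tb[[col]]))
  bad <- which(is.na(x) & !is.na(tb[[col]]) & tb[[col]] != "")
  bad <- c(bad, which(is.na(tb[[col]])))
  if (length(bad)) {
    stop("non-numeric value in column '", col, "' of ", path,
         " (line ", min(bad) + 1L, ")", call. = FALSE)
  }
  x
}

#' Read a compound table
#'
#' Tab-separated with a header; required column `compound_id`, optional
#' `inchikey` (27-character standard InChIKey), `name`, `smiles` and
#' `coa_carrier` (boolean flagging Coenzyme-A-carrying compounds). Extra
#' columns are ignored.
#'
#' @param path TSV file path
#' @return data.frame
#' @export
readCompoundTable <- function(path) {
  tb <- .readTsv(path)
  if (!"compound_id" %in% names(tb)) {
    stop("compound table ", path, " lacks required column 'compound_id'",
         call. = FALSE)
  }
  if ("coa_carrier" %in% names(tb)) {
    tb$coa_carrier <- tb$coa_carrier %in% c(TRUE, "TRUE", "true", "1", 1)
  }
  tb
}

#' CoA-carrying compound ids of a compound table
#'
#' @param compounds compound table (see [readCompoundTable()])
#' @return character vector of ids flagged `coa_carrier`
#' @export
coaCarriers <- function(compounds) {
  if (is.null(compounds$coa_carrier)) return(character(0))
  as.character(compounds$compound_id[compounds$coa_carrier])
}

#' Read a reactant-product pair table
#'
#' Two dialects are accepted (auto-detected unless forced):
#' \describe{
#'   \item{counts}{columns `substrate_id`, `product_id`, `n_c`, `n_r`,
#'     `n_p` (plus `reaction_id`); the CAR is recomputed from the counts
#'     with [computeCAR()], and cross-checked against any `car` column
#'     (mismatch above 1e-6 raises a warning).}
#'   \item{weighted}{columns `substrate_id`, `product_id`, `car` — the
#'     pre-weighted form in which curated networks are distributed; counts
#'     stay absent.}
#' }
#' Extra columns are ignored; malformed numeric fields and CARs outside
#' `[0, 1]` are hard errors naming the offending line.
#'
#' @param path TSV file path
#' @param dialect `"auto"`, `"counts"` or `"weighted"`
#' @return pair table data.frame with a `car` column
#' @export
readPairTable <- function(path, dialect = c("auto", "counts", "weighted")) {
  dialect <- match.arg(dialect)
  tb <- .readTsv(path)
  # graph dumps are a pair table under other column names
  ren <- c(node_a = "substrate_id", node_b = "product_id",
           reaction_ids = "reaction_id")
  for (from in names(ren)) {
    if (from %in% names(tb) && !ren[[from]] %in% names(tb)) {
      names(tb)[names(tb) == from] <- ren[[from]]
    }
  }
  need <- c("substrate_id", "product_id")
  if (!all(need %in% names(tb))) {
    stop("pair table ", path, " lacks required column(s) ",
         paste(setdiff(need, names(tb)), collapse = ", "), call. = FALSE)
  }
  hasCounts <- all(c("n_c", "n_r", "n_p") %in% names(tb))
  if (dialect == "auto") dialect <- if (hasCounts) "counts" else "weighted"
  if (is.null(tb$reaction_id)) {
    tb$reaction_id <- rep(NA_character_, nrow(tb))
  }
  if (dialect == "counts") {
    if (!hasCounts) {
      stop("pair table ", path, " lacks count columns n_c/n_r/n_p",
           call. = FALSE)
    }
    n_c <- .numericColumn(tb, "n_c", path)
    n_r <- .numericColumn(tb, "n_r", path)
    n_p <- .numericColumn(tb, "n_p", path)
    car <- computeCAR(n_c, n_r, n_p)
    if ("car" %in% names(tb)) {
      given <- .numericColumn(tb, "car", path)
      off <- which(abs(given - car) > 1e-6)
      if (length(off)) {
        warning("car column of ", path, " disagrees with counts on ",
                length(off), " row(s) (first at line ", off[1] + 1L,
                "); counts take precedence", call. = FALSE)
      }
    }
    tb$car <- car
  } else {
    if (!"car" %in% names(tb)) {
      stop("pair table ", path, " has neither counts nor a car column",
           call. = FALSE)
    }
    tb$car <- .numericColumn(tb, "car", path)
    bad <- which(tb$car < 0 | tb$car > 1)
    if (length(bad)) {
      stop("car outside [0, 1] in ", path, " (line ", bad[1] + 1L, ")",
           call. = FALSE)
    }
  }
  tb
}

#' Write a pair table
#'
#' Full-precision machine dialect: reload with [readPairTable()] reproduces
#' identical in-memory values.
#'
#' @param pairs pair table (e.g. from [decomposeReactions()])
#' @param path output TSV path
#' @export
writePairTable <- function(pairs, path) {
  cols <- intersect(c("reaction_id", "substrate_id", "product_id",
                      "n_c", "n_r", "n_p", "car_r", "car_p", "car"),
                    names(pairs))
  tb <- pairs[, cols, drop = FALSE]
  for (col in intersect(c("car_r", "car_p", "car"), cols)) {
    tb[[col]] <- formatC(tb[[col]], format = "g", digits = 17)
  }
  .writeTsv(tb, path)
}

#' Write a graph edge dump
#'
#' Edge-list TSV with columns `node_a`, `node_b`, `car`, `distance`,
#' `reaction_ids` in deterministic order (see [edgeTable()]).
#'
#' @param graph a [PairGraph-class]
#' @param path output TSV path
#' @export
writeGraphDump <- function(graph, path) {
  tb <- edgeTable(graph)
  tb$car <- formatC(tb$car, format = "g", digits = 17)
  tb$distance <- formatC(tb$distance, format = "g", digits = 17)
  .writeTsv(tb, path)
}

#' Write a ranked pathway table
#'
#' Mirrors the ranked search output layout: columns `index`,
#' `pathway_length`, `intermediates`, `reaction_ids`, `pathway_score`,
#' `average_car`. Report mode rounds score and average CAR to two decimals
#' (round-half-even); machine mode keeps full precision. An empty result
#' writes the header only.
#'
#' @param pathways a [PathwaySet-class]
#' @param path output TSV path
#' @param mode `"report"` or `"machine"`
#' @export
writePathwayTable <- function(pathways, path, mode = c("report", "machine")) {
  mode <- match.arg(mode)
  tb <- as.data.frame(pathways)
  if (mode == "report") {
    tb$pathway_score <- formatRound2(tb$pathway_score)
    tb$average_car <- formatRound2(tb$average_car)
  } else {
    tb$pathway_score <- formatC(tb$pathway_score, format = "g", digits = 17)
    tb$average_car <- formatC(tb$average_car, format = "g", digits = 17)
  }
  .writeTsv(tb, path)
}

#' Dump a PathwaySet as JSON
#'
#' Machine-readable dump with the full reaction-id sets and the per-step
#' CARs and distances of every pathway.
#'
#' @param pathways a [PathwaySet-class]
#' @param path output JSON path
#' @export
writePathwayJSON <- function(pathways, path) {
  obj <- list(
    source = pathways@source, target = pathways@target,
    transform = pathways@transform, k = pathways@k,
    pathways = lapply(seq_along(pathways@pathways), function(i) {
      p <- pathways@pathways[[i]]
      list(rank = i, nodes = p$nodes, reactions = p$reactions,
           step_cars = p$stepCars, step_distances = p$stepDistances,
           score = p$score, average_car = p$averageCar, length = p$length)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a labelled pair table for ROC validation
#'
#' Columns `substrate_id`, `product_id`, `car`, `is_main` (0/1 or logical).
#'
#' @param path TSV file path
#' @return data.frame
#' @export
readLabeledPairs <- function(path) {
  tb <- .readTsv(path)
  need <- c("car", "is_main")
  if (!all(need %in% names(tb))) {
    stop("labelled pair table ", path, " lacks column(s) ",
         paste(setdiff(need, names(tb)), collapse = ", "), call. = FALSE)
  }
  tb$car <- .numericColumn(tb, "car", path)
  tb$is_main <- tb$is_main %in% c(TRUE, "TRUE", "true", "1", 1)
  tb
}

#' Write a RocTable with its summary block
#'
#' The per-cutoff table goes to `path`; AUC, optimal cutoff and maximal
#' Youden's index go to `summaryPath` (flat `key=value` lines) when given.
#'
#' @param roc a [RocTable-class]
#' @param path output TSV path for the per-cutoff table
#' @param summaryPath optional path for the summary block
#' @export
writeRocTable <- function(roc, path, summaryPath = NULL) {
  .writeTsv(rocPoints(roc), path)
  if (!is.null(summaryPath)) {
    writeLines(c(
      sprintf("auc=%.17g", roc@auc),
      sprintf("optimal_cutoff=%.17g", roc@optimalCutoff),
      sprintf("youden_max=%.17g", roc@youdenMax),
      sprintf("n_positive=%d", roc@nPositive),
      sprintf("n_negative=%d", roc@nNegative)), summaryPath)
  }
  invisible(path)
}

#' Read a run configuration
#'
#' YAML (preferred) or flat `key=value` lines. Recognised keys: `network`,
#' `compounds`, `transform`, `k`, `max_length`, `car_threshold`,
#' `exclusions` (list or comma-separated), `cofactors` (path to a cofactor
#' list for benchmark networks), `out`, `seed`, `verbosity`. Missing keys
#' fall back to the standard configuration: default transform, k = 10,
#' max_length = 100, CAR threshold 0.34, free CoA (C00010) excluded.
#'
#' @param path config file path, or `NULL` for pure defaults
#' @return named list of settings
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(network = NULL, compounds = NULL, transform = "default",
                   k = 10L, max_length = 100L, car_threshold = 0.34,
                   exclusions = "C00010", cofactors = NULL, out = NULL,
                   seed = NULL, verbosity = 1L)
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  cfg <- if (any(grepl("^[^#=]+=[^=]*$", txt)) && !any(grepl(":", txt))) {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) trimws(p[2])),
                    vapply(parts, function(p) trimws(p[1]), ""))
  } else {
    yaml::yaml.load(paste(txt, collapse = "\n"))
  }
  for (nm in names(cfg)) {
    if (nm %in% c("k", "max_length", "verbosity", "seed")) {
      cfg[[nm]] <- as.integer(cfg[[nm]])
    }
    if (nm == "car_threshold") cfg[[nm]] <- as.numeric(cfg[[nm]])
    if (nm == "exclusions" && is.character(cfg[[nm]]) &&
        length(cfg[[nm]]) == 1L) {
      cfg[[nm]] <- trimws(strsplit(cfg[[nm]], ",", fixed = TRUE)[[1]])
    }
  }
  utils::modifyList(defaults, cfg)
}
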
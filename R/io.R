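# Readers and writers for the pipeline's tabular interchange formats.
# All tables are RFC-4180 CSV with a header row, UTF-8, "." decimal
# separator; nondetect Cq is an empty cell or the literal token "ND".

ND_TOKENS <- c("", "ND", "NA")

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab
}

num_col <- function(x) suppressWarnings(as.numeric(x))

#' Read a qPCR reaction table
#'
#' Expects columns \code{assay}, \code{sample_id}, \code{role},
#' \code{run_id}, \code{batch_id}, \code{dilution}, \code{cq}. Nondetect
#' reactions are encoded as an empty cell or \code{"ND"} and returned as NA
#' (never a numeric sentinel). \code{role} distinguishes field samples
#' (\code{"sample"}) from controls (\code{"NTC"}, \code{"NEC"}, \code{"PC"},
#' \code{"standard"}).
#'
#' @param path CSV file path.
#' @return data.frame of reactions with numeric \code{dilution} and
#'   \code{cq}.
#' @export
read_reaction_table <- function(path) {
  tab <- read_csv_checked(path, c("assay", "sample_id", "role", "run_id",
                                  "batch_id", "dilution", "cq"))
  tab$dilution <- num_col(tab$dilution)
  bad <- which(!is.finite(tab$dilution) | tab$dilution <= 0)
  if (length(bad)) {
    stop("validation error in ", basename(path), ": nonpositive or ",
         "missing dilution factor at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  cq_raw <- trimws(tab$cq)
  tab$cq <- num_col(cq_raw)
  not_nd <- !(toupper(cq_raw) %in% ND_TOKENS)
  garbled <- which(not_nd & is.na(tab$cq))
  if (length(garbled)) {
    stop("validation error in ", basename(path), ": unparseable Cq at ",
         "row(s) ", paste(utils::head(garbled, 5), collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Write a qPCR reaction table
#'
#' Inverse of \code{\link{read_reaction_table}}; nondetects are written as
#' the token \code{"ND"}.
#'
#' @param reactions data.frame of reactions.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_reaction_table <- function(reactions, path) {
  out <- reactions
  out$cq <- ifelse(is.na(out$cq), "ND", format(out$cq, digits = 15,
                                               scientific = FALSE,
                                               trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plate-count table
#'
#' Expects columns \code{sample_id}, \code{volume_ml}, \code{count},
#' \code{tntc}; TNTC plates carry an empty count and \code{tntc = TRUE}.
#'
#' @param path CSV file path.
#' @return data.frame with numeric \code{volume_ml}, \code{count} and
#'   logical \code{tntc}.
#' @export
read_plate_table <- function(path) {
  tab <- read_csv_checked(path, c("sample_id", "volume_ml", "count",
                                  "tntc"))
  tab$volume_ml <- num_col(tab$volume_ml)
  if (any(!is.finite(tab$volume_ml) | tab$volume_ml <= 0)) {
    stop("validation error in ", basename(path),
         ": plate volumes must be positive", call. = FALSE)
  }
  tab$count <- num_col(tab$count)
  tab$tntc <- toupper(trimws(tab$tntc)) %in% c("TRUE", "T", "1", "YES")
  tab
}

#' Write result tables and a run manifest
#'
#' Writes one CSV per result family (e.g. concentration estimates, effect
#' estimates) and a JSON manifest recording the files, the configuration,
#' the seed and the package version. Identical inputs produce byte-identical
#' outputs.
#'
#' @param results named list of data.frames.
#' @param dir output directory (created if needed).
#' @param config optional \code{run_config}/list stored in the manifest.
#' @param seed optional integer seed stored in the manifest.
#' @return invisible character vector of files written.
#' @export
write_results <- function(results, dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      stop("write_results: cannot create output directory ", dir,
           call. = FALSE)
    }
  }
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], f, row.names = FALSE,
                     fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  manifest <- list(
    files = basename(files),
    seed = seed,
    config = config,
    package = "mstquant",
    version = as.character(utils::packageVersion("mstquant")))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(files, mf))
}

#' Validated pipeline run configuration
#'
#' @param seed integer RNG seed.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param cutoff_grid list with \code{min_cq} and per-assay \code{max_cq}
#'   (named integer vector); requires \code{10 <= min_cq < max_cq}.
#' @param detection_response_threshold detection fraction below which the
#'   risk models switch to a binary response; in (0, 1].
#' @param paths named list of input table paths.
#' @param output_dir output directory.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L,
                       mcmc = mcmc_config(seed = seed),
                       cutoff_grid = list(min_cq = 10L,
                                          max_cq = c(target1 = 40L)),
                       detection_response_threshold = 0.75,
                       paths = list(), output_dir = "results") {
  if (cutoff_grid$min_cq < 10L || any(cutoff_grid$max_cq <=
                                      cutoff_grid$min_cq)) {
    stop("run_config: need 10 <= min_cq < max_cq", call. = FALSE)
  }
  if (detection_response_threshold <= 0 ||
      detection_response_threshold > 1) {
    stop("run_config: detection_response_threshold must lie in (0, 1]",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), mcmc = mcmc,
                 cutoff_grid = cutoff_grid,
                 detection_response_threshold = detection_response_threshold,
                 paths = paths, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  mc <- raw$mcmc
  mcmc <- if (is.null(mc)) {
    mcmc_config(seed = raw$seed %||% 1L)
  } else {
    mcmc_config(mc$chains %||% 4L, mc$warmup %||% 2000L,
                mc$sampling %||% 2000L, seed = raw$seed %||% 1L)
  }
  cg <- raw$cutoff_grid %||% list(min_cq = 10L, max_cq = c(target1 = 40L))
  if (!is.null(cg$max_cq)) cg$max_cq <- unlist(cg$max_cq)
  run_config(seed = raw$seed %||% 1L, mcmc = mcmc, cutoff_grid = cg,
             detection_response_threshold =
               raw$detection_response_threshold %||% 0.75,
             paths = raw$paths %||% list(),
             output_dir = raw$output_dir %||% "results")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
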
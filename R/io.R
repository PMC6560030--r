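# Plain-text input/output: BIDS-style events TSV and artifact files
# carrying a configuration hash for provenance.

#' Write a BIDS-style events TSV
#'
#' Writes `onset` and `duration` first, a `trial_type` column (the state,
#' or the category for localizer trials), and any further metadata columns.
#'
#' @param events event data.frame.
#' @param path output path.
#' @param trialType name of the column to expose as `trial_type`.
#' @return invisibly, the path.
#' @export
writeEventsTsv <- function(events, path, trialType = "state") {
  ev <- as.data.frame(events)
  stopIfNot(all(c("onset", "duration") %in% names(ev)),
            "events need 'onset' and 'duration' columns")
  tt <- if (trialType %in% names(ev)) ev[[trialType]] else
    rep("event", nrow(ev))
  rest <- setdiff(names(ev), c("onset", "duration"))
  out <- cbind(data.frame(onset = ev$onset, duration = ev$duration,
                          trial_type = tt), ev[rest])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#' @param path file path.
#' @return data.frame.
#' @export
readEventsTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# ---- hashed pipeline artifacts ----------------------------------------

writeArtifactTsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readArtifactTsv <- function(path, hash, stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '", stage,
         "' first", call. = FALSE)
  first <- readLines(path, n = 1)
  found <- sub("^# config_hash=", "", first)
  if (!identical(found, hash))
    stop("artifact '", basename(path), "' was produced under a different ",
         "configuration; refusing to mix artifacts", call. = FALSE)
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

writeArtifactJson <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

readArtifactJson <- function(path, hash, stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '", stage,
         "' first", call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$config_hash, hash))
    stop("artifact '", basename(path), "' was produced under a different ",
         "configuration; refusing to mix artifacts", call. = FALSE)
  x
}
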
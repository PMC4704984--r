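# Report and table writers. Convention: summary reports round currency to
# 2 dp, probabilities to 3 dp and thresholds to 2 dp; raw data exports
# (PSA draws, CE plane) are written at full precision so that re-importing
# reproduces the values.

.write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.write_csv_rounded <- function(df, path, digits = list()) {
  out <- df
  for (nm in names(digits)) {
    if (nm %in% names(out)) out[[nm]] <- round(out[[nm]], digits[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Manifest sufficient to reproduce each output (given the same package
# version): subcommand, config provenance and content hash, seeds and
# iteration counts, output file list.
.write_manifest <- function(dir, subcommand, config_path, seed, extra = list(),
                            outputs = character()) {
  config_hash <- if (is.null(config_path)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    write_config(default_config(), tmp)
    .hash31(paste(readLines(tmp), collapse = "\n"))
  } else {
    .hash31(paste(readLines(config_path), collapse = "\n"))
  }
  manifest <- c(
    list(
      subcommand = subcommand,
      config = config_path %||% "packaged-default",
      config_hash = config_hash,
      seed = seed,
      outputs = as.list(outputs),
      package = "stepcea",
      version = as.character(utils::packageVersion("stepcea")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      sign_convention = "deltas are comparator minus reference; positive incremental NMB favours the comparator"
    ),
    extra
  )
  path <- file.path(dir, paste0(subcommand, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
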
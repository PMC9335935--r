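# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Integer mix used to give independent random substreams to simulation
#' layers and to individual sites, so that enlarging one layer never
#' perturbs draws in another. Kept below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param k substream counter (site index or layer id)
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, k) {
  # 48271 is the classic Lehmer multiplier; arithmetic in double stays exact
  # well beyond these magnitudes
  as.integer((abs(as.double(seed)) * 48271 + 1103 * as.double(k) + 12345) %%
               2147483647)
}

stop_config <- function(...) {
  stop(structure(class = c("sdrscan_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("sdrscan_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# light-weight config hash for output provenance headers: FNV-1a over the
# deparsed object, reduced to hex
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

write_tsv_with_header <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# produced by sdrscan %s",
                     as.character(utils::packageVersion("sdrscan"))), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config hash: %s", config_hash(config)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
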
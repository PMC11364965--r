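# Independent oracles and small in-code fixtures shared across tests.

# Exhaustive double-loop matcher: the reference implementation that
# match_features() must agree with. Deliberately O(n*m) and index-based.
brute_force_match <- function(table, entries, tol) {
  hits <- data.frame(row_index = integer(0), compound = character(0),
                     rule = character(0))
  for (i in seq_len(nrow(table))) {
    for (j in seq_len(nrow(entries))) {
      tol_da <- if (tol$unit == "da") tol$value else
        entries$theoretical_mz[j] * tol$value / 1e6
      if (abs(table$mz[i] - entries$theoretical_mz[j]) <= tol_da + 1e-9) {
        hits <- rbind(hits, data.frame(
          row_index = table$row_index[i],
          compound = entries$compound[j],
          rule = entries$rule[j], stringsAsFactors = FALSE))
      }
    }
  }
  hits
}

# Canonical key set for comparing two annotation tables.
match_keys <- function(df) {
  sort(paste(df$row_index, df$compound, df$rule, sep = "|"))
}

# A tiny in-code compound db (no file I/O) for unit tests.
tiny_db <- function() {
  compound_db(data.frame(
    name = c("alpha", "beta", "gamma"),
    class = c("auxins", "cytokinins", "auxins"),
    formula = c("C10H9NO2", "C10H13N5O", "C12H13NO2"),
    monoisotopic_mass = c(175.063329, 219.112012, 203.094629),
    predicted_rt = c(4.2, 3.3, 6.05),
    stringsAsFactors = FALSE), provenance = "test")
}

write_temp_csv <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, ...)
  path
}
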
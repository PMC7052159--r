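#' Write a replicated count table as long-format TSV
#'
#' Columns \code{otu_id}, \code{sample_id}, \code{replicate_id},
#' \code{count}; zero cells are omitted.
#'
#' @param raw a \code{\link{replicate_count_table}}.
#' @param path output file.
#' @export
write_counts_tsv <- function(raw, path) {
  stopifnot(inherits(raw, "replicate_count_table"))
  idx <- which(raw$counts > 0, arr.ind = TRUE)
  df <- data.frame(otu_id = dimnames(raw$counts)[[1L]][idx[, 1L]],
                   sample_id = dimnames(raw$counts)[[2L]][idx[, 2L]],
                   replicate_id = idx[, 3L],
                   count = raw$counts[idx])
  df <- df[order(df$otu_id, df$sample_id, df$replicate_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replicated count table from long-format TSV
#'
#' @param counts_path TSV with columns \code{otu_id}, \code{sample_id},
#'   \code{replicate_id}, \code{count}.
#' @param meta_path TSV with columns \code{sample_id}, \code{species},
#'   \code{batch}, \code{primer}, \code{is_blank}, \code{blank_kind}.
#' @return a \code{\link{replicate_count_table}}.
#' @export
read_count_table <- function(counts_path, meta_path) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("otu_id", "sample_id", "replicate_id", "count")
  if (!all(need %in% names(df))) {
    stop("counts TSV needs columns: ", paste(need, collapse = ", "))
  }
  otus <- sort(unique(df$otu_id))
  samples <- unique(meta$sample_id)
  R <- max(df$replicate_id)
  a <- array(0L, dim = c(length(otus), length(samples), R),
             dimnames = list(otus, samples, NULL))
  a[cbind(match(df$otu_id, otus), match(df$sample_id, samples),
          df$replicate_id)] <- df$count
  meta$is_blank <- as.logical(meta$is_blank)
  replicate_count_table(a, meta)
}

#' Write per-individual diet profiles as TSV
#'
#' @param profiles a \code{diet_profiles} object from
#'   \code{\link{to_profiles}}.
#' @param path output file; wide format, one row per sample.
#' @export
write_profiles_tsv <- function(profiles, path) {
  stopifnot(inherits(profiles, "diet_profiles"))
  df <- data.frame(sample_id = rownames(profiles$p),
                   species = profiles$meta$species,
                   profiles$p, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
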
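# File formats. Interval files on disk follow BED conventions (0-based,
# half-open); everything user-facing inside the package is 1-based
# inclusive. The conversion happens in read_bed()/write_bed() and nowhere
# else.

#' Read a chrom.sizes file
#'
#' Two-column whitespace-delimited text: chromosome name, length in bp.
#'
#' @param path file path.
#' @return data frame with columns `name`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop(sprintf("'%s': expected two columns (name, length)", path))
  if (!is.numeric(d[[2]]))
    stop(sprintf("'%s': second column must be numeric lengths", path))
  stats::setNames(d[, 1:2], c("name", "length"))
}

#' Write a chrom.sizes file from a binned genome
#' @param genome a [bin_genome()] object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(genome$chroms, format(genome$lengths, scientific = FALSE,
                                     trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read minimal BEDPE read pairs
#'
#' Four tab/space-separated columns: chrom1, pos1, chrom2, pos2 (1-based
#' bp). A single header line is tolerated and skipped when columns 2/4
#' are not numeric. Gzip-compressed files are read transparently.
#' Malformed lines raise an error naming the line number.
#'
#' @param path file path (plain or `.gz`).
#' @return data frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
read_bedpe <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  skip <- 0L
  if (length(lines)) {
    f1 <- strsplit(lines[1], "[ \t]+")[[1]]
    if (length(f1) >= 4 &&
        (is.na(suppressWarnings(as.numeric(f1[2]))) ||
         is.na(suppressWarnings(as.numeric(f1[4])))))
      skip <- 1L
  }
  body <- lines[seq_len(length(lines)) > skip]
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(chrom1 = character(0), pos1 = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(body, "[ \t]+")
  nf <- lengths(f)
  if (any(nf < 4)) {
    i <- which(nf < 4)[1]
    stop(sprintf("'%s' line %d: expected 4 fields, found %d",
                 path, i + skip, nf[i]))
  }
  m <- matrix(unlist(lapply(f, `[`, 1:4)), ncol = 4, byrow = TRUE)
  p1 <- suppressWarnings(as.numeric(m[, 2]))
  p2 <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(p1) || anyNA(p2)) {
    i <- which(is.na(p1) | is.na(p2))[1]
    stop(sprintf("'%s' line %d: non-numeric coordinate", path, i + skip))
  }
  data.frame(chrom1 = m[, 1], pos1 = p1, chrom2 = m[, 3], pos2 = p2,
             stringsAsFactors = FALSE)
}

#' Write minimal BEDPE read pairs
#' @param pairs data frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @param path output path (gzip when it ends in `.gz`).
#' @export
write_bedpe <- function(pairs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s\t%s\t%s", pairs$chrom1,
                     format(pairs$pos1, scientific = FALSE, trim = TRUE),
                     pairs$chrom2,
                     format(pairs$pos2, scientific = FALSE, trim = TRUE)),
             con)
  invisible(path)
}

#' Read a BED interval file into 1-based inclusive coordinates
#'
#' @param path BED3+ file (0-based, half-open on disk).
#' @return data frame `chrom`, `start`, `end` (1-based inclusive), plus
#'   `name`, `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(d) < 3) stop(sprintf("'%s': BED needs at least 3 columns", path))
  out <- data.frame(chrom = d[[1]], start = d[[2]] + 1, end = d[[3]],
                    stringsAsFactors = FALSE)
  extra <- c("name", "score", "strand")
  for (j in seq_len(min(ncol(d) - 3, 3)))
    out[[extra[j]]] <- d[[3 + j]]
  out
}

#' Write 1-based inclusive intervals as a BED file
#' @param intervals data frame `chrom`, `start`, `end` (1-based inclusive),
#'   optional `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  d <- data.frame(intervals$chrom,
                  format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                  format(intervals$end, scientific = FALSE, trim = TRUE))
  for (col in c("name", "score", "strand"))
    if (col %in% names(intervals)) d[[col]] <- intervals[[col]]
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

matrix_with_labels <- function(m, genome) {
  dimnames(m) <- list(bin_labels(genome), bin_labels(genome))
  m
}

#' Persist a contact matrix as dense TSV
#'
#' Bin labels `chrom:start-end` on both axes; integer counts. The
#' round trip through [read_contact_matrix()] is lossless.
#'
#' @param contacts a [build_contact_matrix()] object.
#' @param path output path.
#' @export
write_contact_matrix <- function(contacts, path) {
  m <- matrix_with_labels(contacts$counts, contacts$genome)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param genome the [bin_genome()] the matrix was written against.
#' @param condition optional condition label to restore.
#' @return a `contact_matrix` object.
#' @export
read_contact_matrix <- function(path, genome, condition = NA_character_) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  if (!identical(unname(dim(m)), rep(genome$n_bins, 2L)))
    stop(sprintf("'%s': matrix is %dx%d but genome has %d bins",
                 path, nrow(m), ncol(m), genome$n_bins))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  structure(list(genome = genome, counts = m, condition = condition,
                 n_input = NA_integer_, n_duplicates = NA_integer_,
                 n_retained = sum(m[upper.tri(m, diag = TRUE)])),
            class = "contact_matrix")
}

#' Persist a Z-score matrix as dense TSV
#'
#' Unobserved cells (mask `FALSE`) are written as `NA`, which keeps them
#' distinguishable from genuinely observed cells whose Z is numerically 0;
#' observed values are written with 17 significant digits, so the round
#' trip through [read_zscore_matrix()] restores Z bit-stably (well within
#' 1e-12).
#'
#' @param z a [zscore_transform()] object.
#' @param path output path.
#' @export
write_zscore_matrix <- function(z, path) {
  m <- z$z
  m[!z$mask] <- NA
  m <- matrix_with_labels(m, z$genome)
  df <- format(m, digits = 17, trim = TRUE, scientific = TRUE)
  df[is.na(m)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_zscore_matrix
#' @param genome the [bin_genome()] the matrix was written against.
#' @param condition optional condition label to restore.
#' @return a `zscore_matrix` object.
#' @export
read_zscore_matrix <- function(path, genome, condition = NA_character_) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  if (!identical(unname(dim(m)), rep(genome$n_bins, 2L)))
    stop(sprintf("'%s': matrix is %dx%d but genome has %d bins",
                 path, nrow(m), ncol(m), genome$n_bins))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  mask <- !is.na(m)
  m[!mask] <- 0
  structure(list(genome = genome, z = m, mask = mask,
                 condition = condition),
            class = "zscore_matrix")
}

#' Export hot/cold region calls
#'
#' Writes a BED file of the called regions (coordinates converted to
#' 0-based half-open at this boundary) and a region table TSV with
#' 1-based inclusive coordinates and interaction frequencies printed as
#' percentages with 4 decimal places.
#'
#' @param calls a [call_regions()] result.
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @export
write_region_calls <- function(calls, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    b <- data.frame(chrom = calls$chrom, start = calls$start,
                    end = calls$end,
                    name = sprintf("%s_%d", calls$call, calls$rank),
                    score = sprintf("%.4f", calls$frequency_pct),
                    stringsAsFactors = FALSE)
    write_bed(b, bed_path)
  }
  if (!is.null(tsv_path)) {
    d <- data.frame(chrom = calls$chrom,
                    start = format(calls$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(calls$end, scientific = FALSE, trim = TRUE),
                    call = calls$call, rank = calls$rank,
                    frequency_pct = sprintf("%.4f", calls$frequency_pct),
                    stringsAsFactors = FALSE)
    utils::write.table(d, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(calls)
}

#' Export differential calls as BEDPE-style TSV
#'
#' One row per call: both bins (0-based half-open), the type, the
#' relative ratio (2 decimals, the conventional display precision) and
#' the two condition Z-scores.
#'
#' @param calls a [classify_differential()] result.
#' @param path output path.
#' @export
write_differential_calls <- function(calls, path) {
  d <- data.frame(
    chrom1 = calls$chrom1,
    start1 = format(calls$start1 - 1, scientific = FALSE, trim = TRUE),
    end1 = format(calls$end1, scientific = FALSE, trim = TRUE),
    chrom2 = calls$chrom2,
    start2 = format(calls$start2 - 1, scientific = FALSE, trim = TRUE),
    end2 = format(calls$end2, scientific = FALSE, trim = TRUE),
    type = calls$type,
    ratio = sprintf("%.2f", calls$ratio),
    z_T0 = sprintf("%.6g", calls$z0),
    z_T1 = sprintf("%.6g", calls$z1),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a gain/loss profile as bedGraph-style TSV
#'
#' Two four-column bedGraph tracks in one file distinguished by a track
#' column: per-bin gained (positive) and lost (negative) interaction
#' counts.
#'
#' @param profile a [gain_loss_profile()] data frame.
#' @param path output path.
#' @export
write_gain_loss_bedgraph <- function(profile, path) {
  d <- data.frame(
    chrom = rep(profile$chrom, 2),
    start = format(rep(profile$start, 2) - 1, scientific = FALSE,
                   trim = TRUE),
    end = format(rep(profile$end, 2), scientific = FALSE, trim = TRUE),
    value = c(profile$gains, profile$losses),
    track = rep(c("gain", "loss"), each = nrow(profile)),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export enrichment results as a heatmap-ready matrix
#'
#' Reshapes a long table of [enrichment_test()] rows (stacked over marks
#' and parts) into a marks x (part, set) matrix of T statistics and
#' writes both the long TSV and the matrix TSV.
#'
#' @param results data frame of stacked [enrichment_test()] rows.
#' @param long_path,matrix_path output paths (either may be `NULL`).
#' @return the reshaped matrix, invisibly.
#' @export
write_enrichment_results <- function(results, long_path = NULL,
                                     matrix_path = NULL) {
  if (!is.null(long_path))
    utils::write.table(results, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  col <- paste(results$part, results$set, sep = "|")
  marks <- unique(results$mark)
  cols <- unique(col)
  m <- matrix(NA_real_, length(marks), length(cols),
              dimnames = list(marks, cols))
  m[cbind(match(results$mark, marks), match(col, cols))] <- results$statistic
  if (!is.null(matrix_path))
    utils::write.table(m, matrix_path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  invisible(m)
}

#' Serialize / restore a simulation configuration
#'
#' Human-readable JSON round trip of every scalar field of a
#' [sim_config()] (the derived genome is rebuilt on read).
#'
#' @param config a [sim_config()].
#' @param path JSON path.
#' @export
write_sim_config <- function(config, path) {
  keep <- setdiff(names(config), c("genome", "chrom_lengths"))
  obj <- config[keep]
  obj$chrom_lengths <- as.list(config$chrom_lengths)
  obj$mark_effects <- as.list(config$mark_effects)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @return a restored `sim_config` object.
#' @export
read_sim_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(chrom_lengths = unlist(obj$chrom_lengths),
             window = obj$window, depth = obj$depth, alpha = obj$alpha,
             inter_rate = obj$inter_rate, hot_bins = obj$hot_bins,
             hot_boost = obj$hot_boost,
             planted = as.data.frame(obj$planted,
                                     stringsAsFactors = FALSE),
             planted_strength = obj$planted_strength,
             mark_effects = unlist(obj$mark_effects),
             mark_baseline_log2 = obj$mark_baseline_log2,
             mark_baseline_sd = obj$mark_baseline_sd,
             mark_dispersion = obj$mark_dispersion,
             n_genes = obj$n_genes, gene_length = obj$gene_length,
             gene_desert_frac = obj$gene_desert_frac,
             peak_depth = obj$peak_depth,
             peak_coupling = obj$peak_coupling,
             n_breakpoints = obj$n_breakpoints,
             breakpoint_hot_prob = obj$breakpoint_hot_prob,
             expr_mean = obj$expr_mean, expr_sd = obj$expr_sd,
             expr_noise_sd = obj$expr_noise_sd, seed = obj$seed)
}
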
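#' Read a BED3/BED6 file
#'
#' Intervals are returned 0-based half-open; strand is parsed but unused by
#' the pipeline. Chromosome names are matched exactly (no chr-prefix
#' coercion). Malformed lines are reported with their line number.
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (optional columns NA when absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  parse_row <- function(f, ln) {
    if (length(f) < 3L)
      stop("malformed BED line ", ln, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", ln, ": non-numeric coordinates")
    if (s > e) stop("malformed BED line ", ln, ": start > end")
    list(chrom = f[1], start = s, end = e,
         name = if (length(f) >= 4) f[4] else NA_character_,
         score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5]))
         else NA_real_,
         strand = if (length(f) >= 6) f[6] else NA_character_)
  }
  rows <- mapply(parse_row, fields, lineno, SIMPLIFY = FALSE)
  if (!length(rows))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand"))
    if (extra %in% names(df) && !all(is.na(df[[extra]])))
      cols <- c(cols, extra)
  out <- df[, cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' One record per 50 bp step with the value of the 100 bp window anchored at
#' the record start; zero-valued windows are omitted (implicit zeros).
#' Header comment lines carry the chromosome sizes and window geometry so
#' the file round-trips through [read_bedgraph] without external metadata.
#'
#' @param track A [binned_track].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#chrom_sizes=%s",
            paste(sprintf("%s:%d", names(track$chrom_sizes),
                          as.integer(track$chrom_sizes)), collapse = ";")),
    sprintf("#window_bp=%d;step_bp=%d;read_length=%d",
            track$window_bp, track$step_bp, track$read_length),
    "track type=bedGraph"), con)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) next
    s <- (nz - 1L) * track$step_bp
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, s, s + track$step_bp,
                       v[nz]), con)
  }
  invisible(path)
}

#' Read a bedGraph written on the 50 bp step grid
#'
#' Records must align to the step grid (one step per record); gaps are
#' implicit zeros; overlapping (duplicate-start) records are an error.
#'
#' @param path bedGraph path.
#' @param chrom_sizes Named chromosome lengths; defaults to the
#'   `#chrom_sizes` header written by [write_bedgraph].
#' @param window_bp,step_bp,read_length Window geometry; default to header
#'   values, else 100/50/36.
#' @return A [binned_track].
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL, window_bp = NULL,
                          step_bp = NULL, read_length = NULL) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  geom <- c(window_bp = 100L, step_bp = 50L, read_length = 36L)
  for (h in hdr) {
    if (startsWith(h, "#chrom_sizes=") && is.null(chrom_sizes)) {
      parts <- strsplit(sub("^#chrom_sizes=", "", h), ";", fixed = TRUE)[[1]]
      kv <- strsplit(parts, ":", fixed = TRUE)
      chrom_sizes <- stats::setNames(
        vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
        vapply(kv, `[[`, character(1), 1))
    }
    if (startsWith(h, "#window_bp=")) {
      for (kv in strsplit(strsplit(sub("^#", "", h), ";")[[1]], "=")) {
        geom[kv[1]] <- as.integer(kv[2])
      }
    }
  }
  if (is.null(window_bp)) window_bp <- geom[["window_bp"]]
  if (is.null(step_bp)) step_bp <- geom[["step_bp"]]
  if (is.null(read_length)) read_length <- geom[["read_length"]]
  if (is.null(chrom_sizes))
    stop("chrom_sizes not given and no #chrom_sizes header present")
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  values <- lapply(chrom_sizes, function(L)
    numeric(n_windows(L, window_bp, step_bp)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop("malformed bedGraph line ", lineno[i], ": fewer than 4 fields")
    chrom <- f[1]
    if (!chrom %in% names(chrom_sizes))
      stop("bedGraph line ", lineno[i], ": unknown chromosome ", chrom)
    s <- as.numeric(f[2]); e <- as.numeric(f[3]); val <- as.numeric(f[4])
    if (is.na(s) || is.na(e) || is.na(val) || s %% step_bp != 0 ||
        e - s != step_bp)
      stop("bedGraph line ", lineno[i],
           ": record not aligned to the ", step_bp, " bp step grid")
    idx <- s %/% step_bp + 1L
    if (idx > length(values[[chrom]]))
      stop("bedGraph line ", lineno[i], ": record beyond chromosome end")
    if (values[[chrom]][idx] != 0)
      stop("bedGraph line ", lineno[i], ": overlapping records at ",
           chrom, ":", s)
    values[[chrom]][idx] <- val
  }
  binned_track(values, chrom_sizes, window_bp, step_bp, read_length)
}

#' Write a synthetic bundle as a text fixture
#'
#' Writes gene annotation (BED), per-replicate tracks (bedGraph), the
#' expression table (TSV) and ground truth + config echo (JSON) so the
#' bundle round-trips losslessly through the package readers.
#'
#' @param bundle List with `groups`, `truth` and optionally `expression`
#'   (as produced by [simulate_tracks] / [simulate_expression]).
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config] to echo into `config.json`.
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(bundle, dir, config = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stop("cannot create fixture directory ", dir)
  genes <- bundle$truth$genes
  write_bed(data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, name = genes$gene_id),
            file.path(dir, "genes.bed"))
  for (cond in names(bundle$groups)) {
    g <- bundle$groups[[cond]]
    for (r in seq_along(g$tracks))
      write_bedgraph(g$tracks[[r]],
                     file.path(dir, sprintf("%s_rep%d.bedGraph", cond, r)))
  }
  if (!is.null(bundle$expression))
    utils::write.table(bundle$expression, file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth[setdiff(names(bundle$truth),
                                c("genes", "rates"))]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(config)) {
    echo <- config[setdiff(names(config), "domains")]
    echo$chrom_sizes <- as.list(config$chrom_sizes)
    jsonlite::write_json(echo, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture].
#' @return List with `groups`, `truth` (including genes re-read from BED)
#'   and `expression` (NULL when absent).
#' @export
read_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  gb <- read_bed(file.path(dir, "genes.bed"))
  truth$genes <- data.frame(gene_id = gb$name, chrom = gb$chrom,
                            start = gb$start, end = gb$end,
                            stringsAsFactors = FALSE)
  bg <- list.files(dir, pattern = "_rep[0-9]+\\.bedGraph$")
  conds <- unique(sub("_rep[0-9]+\\.bedGraph$", "", bg))
  groups <- list()
  for (cond in conds) {
    files <- sort(bg[startsWith(bg, paste0(cond, "_rep"))])
    tracks <- lapply(files, function(f) read_bedgraph(file.path(dir, f)))
    groups[[cond]] <- replicate_group(tracks, cond)
  }
  expr_path <- file.path(dir, "expression.tsv")
  expression <- if (file.exists(expr_path))
    utils::read.delim(expr_path, stringsAsFactors = FALSE) else NULL
  list(groups = groups, truth = truth, expression = expression)
}

#' Write a run manifest
#'
#' Records the seed, thresholds, configuration echo and input-file MD5
#' checksums of a pipeline run, so outputs can be traced to exactly one
#' provenance record and re-runs reproduce them bit-identically.
#'
#' @param path Output JSON path.
#' @param seed Integer seed the run used.
#' @param thresholds Named list of thresholds (T, composite fraction,
#'   density rule, segment size, ...).
#' @param config Optional configuration echo (list).
#' @param inputs Character vector of input file paths to checksum.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, seed, thresholds = list(), config = NULL,
                           inputs = character(0)) {
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, thresholds = thresholds, config = config,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
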
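#' Write an epoch_set to a portable text container
#'
#' Serializes the full object -- tensor, time base, channel metadata and
#' trial table -- into a single plain-text file organised as named datasets
#' (`/data`, `/times`, `/channels`, `/trials`), mirroring the layout of a
#' hierarchical scientific container while remaining diff-able and
#' dependency-free. Doubles are written with 17 significant digits, which
#' round-trips IEEE-754 values exactly, so `read_epochs(write_epochs(x))`
#' reproduces `x` bitwise.
#'
#' @param x An `epoch_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_epochs()], [export_trials_tsv()]
#' @export
write_epochs <- function(x, path) {
  validate_epoch_set(x)
  d <- dim(x$data)
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  wl("tgmvpa-epochs 1")
  wl("sfreq\t", sprintf("%.17g", x$sfreq))
  wl("dims\t", paste(d, collapse = "\t"))
  wl("dataset /times")
  wl(num(x$times))
  wl("dataset /channels")
  wl(paste(c("name", "type", "roi"), collapse = "\t"))
  ch <- x$channels
  roi <- ifelse(is.na(ch$roi), "NA", ch$roi)
  for (i in seq_len(nrow(ch))) wl(paste(ch$name[i], ch$type[i], roi[i], sep = "\t"))
  wl("dataset /trials")
  tr <- x$trials
  coltype <- vapply(tr, function(col) class(col)[1L], character(1))
  wl(paste(names(tr), collapse = "\t"))
  wl(paste(coltype, collapse = "\t"))
  for (i in seq_len(nrow(tr))) {
    wl(paste(vapply(seq_along(tr), function(j) {
      col <- tr[[j]]
      if (is.na(col[i])) "NA" else if (is.double(col)) sprintf("%.17g", col[i]) else as.character(col[i])
    }, character(1)), collapse = "\t"))
  }
  wl("dataset /data")
  # one line per (trial, channel), trial-major; columns are time samples
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      wl(num(x$data[i, j, ]))
    }
  }
  invisible(path)
}

#' Read an epoch_set from the text container
#'
#' Inverse of [write_epochs()]; validates dataset presence and dimension
#' agreement, and names the offending field on malformed input.
#'
#' @param path File written by [write_epochs()].
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L || lines[1L] != "tgmvpa-epochs 1") {
    stop("not a tgmvpa epochs container (bad magic line): ", path, call. = FALSE)
  }
  field <- function(idx, name) {
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)[[1L]]
    if (parts[1L] != name) stop("malformed container: expected field `", name, "`", call. = FALSE)
    parts[-1L]
  }
  sfreq <- as.numeric(field(2L, "sfreq"))
  dims <- as.integer(field(3L, "dims"))
  if (length(dims) != 3L || anyNA(dims)) stop("malformed container: field `dims`", call. = FALSE)
  ds <- function(name) {
    hit <- which(lines == paste("dataset", name))
    if (length(hit) != 1L) stop("malformed container: missing dataset `", name, "`", call. = FALSE)
    hit
  }
  parse_num_line <- function(line) as.numeric(strsplit(line, "\t", fixed = TRUE)[[1L]])

  i_times <- ds("/times")
  times <- parse_num_line(lines[i_times + 1L])
  if (length(times) != dims[3L]) {
    stop("dataset `/times` has ", length(times), " samples; `dims` says ", dims[3L], call. = FALSE)
  }

  i_ch <- ds("/channels")
  ch_header <- strsplit(lines[i_ch + 1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(ch_header, c("name", "type", "roi"))) {
    stop("dataset `/channels` has unexpected header", call. = FALSE)
  }
  ch_rows <- lines[(i_ch + 2L):(i_ch + 1L + dims[2L])]
  ch <- do.call(rbind, strsplit(ch_rows, "\t", fixed = TRUE))
  if (ncol(ch) != 3L || nrow(ch) != dims[2L]) {
    stop("dataset `/channels` has ", nrow(ch), " rows; `dims` says ", dims[2L], call. = FALSE)
  }
  channels <- tibble::tibble(
    name = ch[, 1L], type = ch[, 2L],
    roi = ifelse(ch[, 3L] == "NA", NA_character_, ch[, 3L])
  )

  i_tr <- ds("/trials")
  tr_names <- strsplit(lines[i_tr + 1L], "\t", fixed = TRUE)[[1L]]
  tr_types <- strsplit(lines[i_tr + 2L], "\t", fixed = TRUE)[[1L]]
  if (length(tr_types) != length(tr_names)) {
    stop("dataset `/trials` column type line does not match header", call. = FALSE)
  }
  tr_rows <- lines[(i_tr + 3L):(i_tr + 2L + dims[1L])]
  cells <- strsplit(tr_rows, "\t", fixed = TRUE)
  ncells <- lengths(cells)
  if (any(ncells != length(tr_names))) {
    stop("dataset `/trials` row ", which(ncells != length(tr_names))[1L],
      " has wrong number of columns",
      call. = FALSE
    )
  }
  mat <- do.call(rbind, cells)
  if (nrow(mat) != dims[1L]) {
    stop("dataset `/trials` has ", nrow(mat), " rows; `dims` says ", dims[1L], call. = FALSE)
  }
  cols <- lapply(seq_along(tr_names), function(j) {
    v <- mat[, j]
    v[v == "NA"] <- NA
    switch(tr_types[j],
      integer = as.integer(v),
      numeric = as.numeric(v),
      logical = as.logical(v),
      factor = ,
      character = as.character(v),
      stop("dataset `/trials` column `", tr_names[j], "` has unsupported type `",
        tr_types[j], "`",
        call. = FALSE
      )
    )
  })
  names(cols) <- tr_names
  trials <- tibble::as_tibble(cols)

  i_da <- ds("/data")
  n_rows <- dims[1L] * dims[2L]
  if (i_da + n_rows > length(lines)) {
    stop("dataset `/data` is truncated: expected ", n_rows, " rows", call. = FALSE)
  }
  da_rows <- lines[(i_da + 1L):(i_da + n_rows)]
  flat <- scan(text = da_rows, sep = "\t", quiet = TRUE)
  if (length(flat) != prod(dims)) {
    stop("dataset `/data` has ", length(flat), " values; `dims` imply ", prod(dims), call. = FALSE)
  }
  # rows are (trial, channel) trial-major with time along columns
  data <- aperm(array(flat, dim = c(dims[3L], dims[2L], dims[1L])), c(3L, 2L, 1L))
  epoch_set(data, times, sfreq, channels, trials)
}

#' Export a trial table as TSV
#'
#' Writes the behavioral trial table with the conventional header
#' (`trial`, `location`, `seen`, `response`, `correct`, `target_present`,
#' plus any extra columns).
#'
#' @param trials Data frame of trials (e.g. `epochs$trials` or the output
#'   of [simulate_behavior()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_trials_tsv <- function(trials, path) {
  tr <- tibble::as_tibble(trials)
  if (!"trial" %in% names(tr)) tr <- dplyr::mutate(tr, trial = dplyr::row_number(), .before = 1L)
  utils::write.table(tr, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}
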
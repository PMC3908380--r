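#' Read a long-format TAP/MS spectral-count table
#'
#' The long TSV dialect has one row per (run, prey) detection with columns
#' \code{run_id}, \code{bait}, \code{prey}, \code{sc}, \code{prey_length},
#' \code{is_control}, \code{condition}. Tab-separated, \code{'.'} decimal,
#' UTF-8; lines starting with \code{#} are ignored. Control runs carry an
#' empty \code{bait} field and \code{is_control = 1}. A control run with no
#' detections is declared by a row with \code{prey} empty and \code{sc = 0}.
#'
#' @param path path to the TSV file.
#' @return A [purification_table()].
#' @export
read_long_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  need <- c("run_id", "bait", "prey", "sc", "prey_length",
            "is_control", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  df$sc <- as.numeric(df$sc)
  if (any(!is.finite(df$sc) | df$sc < 0))
    stop("negative or non-numeric spectral count in ", path)
  df$prey_length <- as.numeric(df$prey_length)

  run_rows <- !duplicated(df$run_id)
  runs <- data.frame(run_id = df$run_id[run_rows],
                     bait = df$bait[run_rows],
                     condition = df$condition[run_rows],
                     is_control = df$is_control[run_rows] %in%
                       c("1", "TRUE", "true", "T"),
                     stringsAsFactors = FALSE)

  counts <- df[nzchar(df$prey), c("run_id", "prey", "sc")]
  names(counts)[2] <- "prey_id"
  key <- paste(counts$run_id, counts$prey_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (run_id, prey) rows in ", path)

  with_len <- df[nzchar(df$prey) & !is.na(df$prey_length), ]
  len_by_prey <- split(with_len$prey_length, with_len$prey)
  bad <- names(len_by_prey)[vapply(len_by_prey,
                                   function(v) length(unique(v)) > 1,
                                   logical(1))]
  if (length(bad))
    stop("inconsistent prey_length for prey(s): ",
         paste(bad, collapse = ", "))
  prey_lengths <- vapply(len_by_prey, `[`, numeric(1), 1)

  purification_table(runs, counts, prey_lengths)
}

#' Write a purification table in the long TSV dialect
#'
#' Inverse of [read_long_tsv()]: the written file reads back to an
#' identical table. Runs without any detection are preserved through a
#' zero-SC placeholder row.
#'
#' @param table a [purification_table()].
#' @param path output path.
#' @export
write_long_tsv <- function(table, path) {
  stopifnot(inherits(table, "purification_table"))
  runs <- table$runs
  cnt <- table$counts[order(table$counts$run_id, table$counts$prey_id), ]
  idx <- match(cnt$run_id, runs$run_id)
  out <- data.frame(run_id = cnt$run_id,
                    bait = runs$bait[idx],
                    prey = cnt$prey_id,
                    sc = cnt$sc,
                    prey_length = table$prey_lengths[cnt$prey_id],
                    is_control = as.integer(runs$is_control[idx]),
                    condition = runs$condition[idx],
                    stringsAsFactors = FALSE)
  empty <- setdiff(runs$run_id, cnt$run_id)
  if (length(empty)) {
    idx <- match(empty, runs$run_id)
    out <- rbind(out, data.frame(run_id = empty, bait = runs$bait[idx],
                                 prey = "", sc = 0, prey_length = NA,
                                 is_control = as.integer(runs$is_control[idx]),
                                 condition = runs$condition[idx]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a SAINT-style input triple
#'
#' Reads the three-file input convention used in the SAINT ecosystem:
#' an interaction file with rows (run_id, bait_name, prey_id, SC), a bait
#' file with rows (run_id, bait_name, T/C flag), and a prey file with rows
#' (prey_id, length[, gene symbol]). All tab-separated, no headers. Runs
#' flagged \code{C} become negative controls; for test runs the bait name
#' becomes the bait group (combined with \code{condition_from} if the bait
#' name encodes a condition suffix as \code{bait_condition}).
#'
#' @param interaction_path,bait_path,prey_path file paths.
#' @param condition_split optional single character; when non-\code{NULL},
#'   bait names are split on its last occurrence into (bait, condition).
#' @return A [purification_table()].
#' @export
read_saint_triple <- function(interaction_path, bait_path, prey_path,
                              condition_split = NULL) {
  bait <- utils::read.delim(bait_path, header = FALSE,
                            colClasses = "character")
  if (ncol(bait) < 3) stop("bait file needs 3 columns (run, bait, T/C)")
  names(bait)[1:3] <- c("run_id", "bait_name", "flag")
  if (!all(bait$flag %in% c("T", "C")))
    stop("bait file flag must be 'T' or 'C', got: ",
         paste(setdiff(bait$flag, c("T", "C")), collapse = ", "))

  prey <- utils::read.delim(prey_path, header = FALSE,
                            colClasses = "character")
  if (ncol(prey) < 2) stop("prey file needs >= 2 columns (prey, length)")
  prey_lengths <- as.numeric(prey[[2]])
  names(prey_lengths) <- prey[[1]]

  inter <- tryCatch(
    utils::read.delim(interaction_path, header = FALSE,
                      colClasses = "character"),
    error = function(e) data.frame(V1 = character(), V2 = character(),
                                   V3 = character(), V4 = character()))
  if (nrow(inter) && ncol(inter) < 4)
    stop("interaction file needs 4 columns (run, bait, prey, SC)")
  if (nrow(inter)) {
    bad <- setdiff(inter[[1]], bait$run_id)
    if (length(bad))
      stop("interaction file references run(s) absent from bait file: ",
           paste(bad, collapse = ", "))
    nolen <- setdiff(inter[[3]], names(prey_lengths))
    if (length(nolen))
      stop("prey(s) without a length entry: ", paste(nolen, collapse = ", "))
  }

  bname <- bait$bait_name
  cond <- rep("", nrow(bait))
  if (!is.null(condition_split)) {
    has <- grepl(condition_split, bname, fixed = TRUE)
    pos <- regexpr(paste0(condition_split, "[^", condition_split, "]*$"),
                   bname)
    cond[has] <- substring(bname[has], pos[has] + 1L)
    bname[has] <- substring(bname[has], 1L, pos[has] - 1L)
  }
  runs <- data.frame(run_id = bait$run_id,
                     bait = ifelse(bait$flag == "C", "", bname),
                     condition = ifelse(bait$flag == "C", "", cond),
                     is_control = bait$flag == "C",
                     stringsAsFactors = FALSE)
  counts <- data.frame(run_id = character(), prey_id = character(),
                       sc = numeric())
  if (nrow(inter))
    counts <- data.frame(run_id = inter[[1]], prey_id = inter[[3]],
                         sc = as.numeric(inter[[4]]),
                         stringsAsFactors = FALSE)
  purification_table(runs, counts, prey_lengths)
}

#' Write a purification table as a SAINT-style triple
#'
#' @param table a [purification_table()].
#' @param interaction_path,bait_path,prey_path output paths.
#' @param condition_split single character used to append the condition to
#'   the bait name (the inverse of the same argument of
#'   [read_saint_triple()]).
#' @export
write_saint_triple <- function(table, interaction_path, bait_path,
                               prey_path, condition_split = "_") {
  stopifnot(inherits(table, "purification_table"))
  runs <- table$runs
  bname <- ifelse(runs$is_control, "CTRL",
                  ifelse(nzchar(runs$condition),
                         paste(runs$bait, runs$condition,
                               sep = condition_split),
                         runs$bait))
  bait <- data.frame(runs$run_id, bname,
                     ifelse(runs$is_control, "C", "T"))
  utils::write.table(bait, bait_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cnt <- table$counts[order(table$counts$run_id, table$counts$prey_id), ]
  idx <- match(cnt$run_id, runs$run_id)
  inter <- data.frame(cnt$run_id, bname[idx], cnt$prey_id, cnt$sc)
  utils::write.table(inter, interaction_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pl <- table$prey_lengths[order(names(table$prey_lengths))]
  utils::write.table(data.frame(names(pl), unname(pl)), prey_path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(interaction_path)
}

#' Read a BioGRID TAB known-interaction reference
#'
#' Parses the BioGRID TAB 2.0/3.0 tab-separated layout, keeping the
#' official symbols of the two interactors and the experimental system
#' type. Pairs are canonicalized as unordered (lexicographically sorted)
#' symbol pairs and deduplicated.
#'
#' @param path path to the TAB file.
#' @param physical_only drop rows whose Experimental System Type is
#'   \code{"genetic"}, keeping physical interactions only (default
#'   \code{TRUE}).
#' @return An object of class \code{known_interactions}: a data.frame with
#'   columns \code{symbol_a}, \code{symbol_b} (sorted within row),
#'   \code{type}, and \code{is_self}.
#' @export
read_biogrid_tab <- function(path, physical_only = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = TRUE,
                          colClasses = "character")
  nm <- tolower(names(df))
  col_a <- grep("official.symbol.interactor.a", nm)[1]
  col_b <- grep("official.symbol.interactor.b", nm)[1]
  col_t <- grep("experimental.system.type", nm)[1]
  if (is.na(col_a) || is.na(col_b))
    stop("not a BioGRID TAB header (no 'Official Symbol Interactor' columns) in ",
         path)
  type <- if (is.na(col_t)) rep("physical", nrow(df)) else df[[col_t]]
  known_interactions(df[[col_a]], df[[col_b]], type,
                     physical_only = physical_only)
}

#' Construct a known-interaction set
#'
#' @param symbol_a,symbol_b character vectors of interactor gene symbols.
#' @param type interaction type per pair ("physical" or "genetic");
#'   recycled.
#' @param physical_only keep only physical interactions.
#' @return A \code{known_interactions} data.frame of canonical unordered
#'   pairs.
#' @export
known_interactions <- function(symbol_a, symbol_b, type = "physical",
                               physical_only = FALSE) {
  type <- rep_len(tolower(as.character(type)), length(symbol_a))
  if (physical_only) {
    keep <- type != "genetic"
    symbol_a <- symbol_a[keep]; symbol_b <- symbol_b[keep]
    type <- type[keep]
  }
  a <- pmin(symbol_a, symbol_b)
  b <- pmax(symbol_a, symbol_b)
  dup <- duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(symbol_a = a[!dup], symbol_b = b[!dup],
                    type = type[!dup],
                    is_self = a[!dup] == b[!dup],
                    stringsAsFactors = FALSE)
  out <- out[order(out$symbol_a, out$symbol_b), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    warning("known-interaction set is empty after filtering")
  class(out) <- c("known_interactions", "data.frame")
  out
}

# canonical "a|b" keys for unordered pairs
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Write a score table to TSV
#'
#' Fixed column order (bait, prey, nsaf, w, z, wd, p, fdr, ppirank, rank,
#' filtered, filter_reason), sorted by rank with filtered rows last;
#' floating columns at 6 significant digits. Header comment lines echo the
#' effective scoring configuration.
#'
#' @param scores a score table as returned by [score_all()] or the
#'   \code{$scores} element of a [ppirank()] fit.
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  cfg <- attr(scores, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    for (k in names(cfg))
      writeLines(sprintf("# %s = %s", k,
                         paste(format(cfg[[k]]), collapse = ",")), con)
  }
  ord <- order(is.na(scores$rank), scores$rank,
               scores$bait_group_id, scores$prey_id)
  out <- scores[ord, c("bait_group_id", "prey_id", "nsaf", "w", "z", "wd",
                       "p_value", "fdr", "ppirank", "rank", "filtered",
                       "filter_reason")]
  names(out) <- c("bait", "prey", "nsaf", "w", "z", "wd", "p", "fdr",
                  "ppirank", "rank", "filtered", "filter_reason")
  for (col in c("nsaf", "w", "z", "wd", "p", "fdr", "ppirank"))
    out[[col]] <- signif(out[[col]], 6)
  out$filtered <- as.integer(out$filtered)
  suppressWarnings(
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ""))
  invisible(path)
}

#' Read back a score table written by [write_score_table()]
#'
#' @param path path to the TSV.
#' @return data.frame with the written columns.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", na.strings = "")
  df$filtered <- as.logical(df$filtered)
  df$filter_reason <- ifelse(is.na(df$filter_reason), "",
                             as.character(df$filter_reason))
  df
}

#' Export scored pairs as a plain edge list
#'
#' Writes (bait, prey, score) for unfiltered pairs, for consumption by
#' network tools.
#'
#' @param scores score table (see [write_score_table()]).
#' @param path output path.
#' @param score_column column to export (default \code{"ppirank"}).
#' @export
write_edge_list <- function(scores, path, score_column = "ppirank") {
  keep <- scores[!scores$filtered, , drop = FALSE]
  keep <- keep[order(-keep[[score_column]], keep$bait_group_id,
                     keep$prey_id), ]
  out <- data.frame(bait = keep$bait, prey = keep$prey_id,
                    score = signif(keep[[score_column]], 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
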
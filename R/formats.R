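# Restraint and configuration file I/O.
#
# NEF (NMR Exchange Format) is STAR-based; no installed R package parses
# STAR, so a minimal tokenizer/reader restricted to RDC restraint-list
# saveframes is implemented here. The legacy fixed format is a
# whitespace table, one residue per row, with six coupling values and six
# errors; 999 is the missing-value sentinel. Column order (pinned
# convention, remappable by argument):
#   C'(i)-N(i+1), C'(i)-H(i+1), N(i)-H(i), CA(i)-C'(i), CA(i)-HA(i),
#   C'(i)-O(i)
# i.e. row i carries the couplings of residue i's plane; the two
# cross-residue vectors reference residue i+1 (on the last row they point
# one residue past the chain and are skipped later, at fitness time).

.LEGACY_SENTINEL <- 999

.starTokens <- function(lines) {
  toks <- character(0L)
  for (ln in lines) {
    ln <- sub("^\\s+", "", ln)
    if (!nchar(ln) || startsWith(ln, "#")) next
    while (nchar(ln)) {
      ln <- sub("^\\s+", "", ln)
      if (!nchar(ln) || startsWith(ln, "#")) break
      ch <- substr(ln, 1L, 1L)
      if (ch == "'" || ch == "\"") {
        m <- regexpr(paste0(ch, "[^", ch, "]*", ch), ln)
        if (m != 1L) stop("malformed STAR quoted string: ", ln)
        len <- attr(m, "match.length")
        toks <- c(toks, substr(ln, 2L, len - 1L))
        ln <- substr(ln, len + 1L, nchar(ln))
      } else {
        m <- regexpr("^\\S+", ln)
        len <- attr(m, "match.length")
        toks <- c(toks, substr(ln, 1L, len))
        ln <- substr(ln, len + 1L, nchar(ln))
      }
    }
  }
  toks
}

# Parse the RDC restraint loops of a NEF/STAR document. Returns a list of
# loops (one per saveframe, in file order), each a data.frame of the
# _nef_rdc_restraint columns.
.parseNefLoops <- function(path) {
  toks <- .starTokens(readLines(path, warn = FALSE))
  loops <- list()
  i <- 1L; nt <- length(toks)
  while (i <= nt) {
    if (toks[i] == "loop_") {
      j <- i + 1L
      tags <- character(0L)
      while (j <= nt && startsWith(toks[j], "_")) {
        tags <- c(tags, toks[j]); j <- j + 1L
      }
      vals <- character(0L)
      while (j <= nt && !toks[j] %in% c("stop_", "loop_", "save_") &&
             !startsWith(toks[j], "save_") && !startsWith(toks[j], "data_")) {
        vals <- c(vals, toks[j]); j <- j + 1L
      }
      if (length(tags) && all(startsWith(tags, "_nef_rdc_restraint."))) {
        if (length(vals) %% length(tags) != 0L)
          stop("malformed NEF loop in ", path, ": ", length(vals),
               " values for ", length(tags), " tags")
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        colnames(m) <- sub("^_nef_rdc_restraint\\.", "", tags)
        loops[[length(loops) + 1L]] <- as.data.frame(m,
                                                     stringsAsFactors = FALSE)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  loops
}

#' Read RDC restraints from NEF file(s)
#'
#' Parses the \code{_nef_rdc_restraint} loops of NEF (STAR) documents. Each
#' qualifying saveframe is one alignment medium; with several paths, media
#' are numbered in path order, then frame order. Any backbone atom-pair
#' combination in \code{\link{vectorTypes}} is accepted; rows with
#' unsupported pairs (and proline amide-H rows, when a sequence is given)
#' are rejected with a warning and counted in the \code{"nSkipped"}
#' attribute.
#'
#' @param paths one or more NEF file paths.
#' @param sequence optional one-letter sequence used to validate residue
#'   names and reject proline N-H rows at parse time.
#' @return an \linkS4class{RdcSet}.
#' @export
readNef <- function(paths, sequence = NULL) {
  loops <- list()
  for (p in paths) loops <- c(loops, .parseNefLoops(p))
  if (!length(loops))
    stop("no nef_rdc_restraint loop found in: ",
         paste(paths, collapse = ", "))
  if (!is.null(sequence)) sequence <- .parseSeq(sequence)
  rows <- list(); nSkip <- 0L
  need <- c("sequence_code_1", "atom_name_1", "sequence_code_2",
            "atom_name_2", "target_value")
  for (m in seq_along(loops)) {
    lp <- loops[[m]]
    miss <- setdiff(need, names(lp))
    if (length(miss))
      stop("NEF loop lacks column(s): ", paste(miss, collapse = ", "))
    unc <- if ("target_value_uncertainty" %in% names(lp))
      suppressWarnings(as.numeric(lp$target_value_uncertainty)) else
        rep(0, nrow(lp))
    unc[is.na(unc)] <- 0
    rec <- data.frame(
      residue_1 = as.integer(lp$sequence_code_1),
      atom_1 = toupper(lp$atom_name_1),
      residue_2 = as.integer(lp$sequence_code_2),
      atom_2 = toupper(lp$atom_name_2),
      medium = rep(m, nrow(lp)),
      value = as.numeric(lp$target_value),
      uncertainty = unc,
      resname_1 = if ("residue_name_1" %in% names(lp))
        toupper(lp$residue_name_1) else NA_character_,
      resname_2 = if ("residue_name_2" %in% names(lp))
        toupper(lp$residue_name_2) else NA_character_,
      stringsAsFactors = FALSE)
    # atom-pair support check (keeps out-of-range residues: they are
    # legitimate during elongation and skipped at fitness time)
    tab <- .vtypeTable()
    key <- c(paste(tab$atom_1, tab$atom_2, tab$offset),
             paste(tab$atom_2, tab$atom_1, -tab$offset))
    ok <- paste(rec$atom_1, rec$atom_2,
                rec$residue_2 - rec$residue_1) %in% key
    if (!is.null(sequence)) {
      n <- length(sequence)
      isPro <- function(r, a) a == "H" & r >= 1L & r <= n &
        sequence[pmin(pmax(r, 1L), n)] == "P"
      pro <- isPro(rec$residue_1, rec$atom_1) |
        isPro(rec$residue_2, rec$atom_2)
      ok <- ok & !pro
      inRange <- rec$residue_1 >= 1L & rec$residue_1 <= n
      chk <- ok & inRange & !is.na(rec$resname_1)
      badName <- chk & rec$resname_1 != .aa1to3(sequence)[
        pmin(pmax(rec$residue_1, 1L), n)]
      if (any(badName))
        warning(sum(badName), " row(s) with residue names inconsistent ",
                "with the sequence")
    }
    if (any(!ok)) {
      warning("medium ", m, ": rejected ", sum(!ok),
              " row(s) with unsupported atom pairs or proline amide H")
      nSkip <- nSkip + sum(!ok)
    }
    rows[[m]] <- rec[ok, , drop = FALSE]
  }
  out <- rdcSet(do.call(rbind, rows))
  attr(out, "nSkipped") <- nSkip
  out
}

#' Write RDC restraints as NEF
#'
#' One \code{nef_rdc_restraint_list} saveframe per alignment medium, in a
#' single STAR document.
#'
#' @param data an \linkS4class{RdcSet}.
#' @param path output file path.
#' @param sequence optional one-letter sequence used to fill residue names
#'   when the records carry none.
#' @param media media to emit (default: those present in the data); a
#'   medium without records gets an empty restraint loop.
#' @return invisibly, \code{path}.
#' @export
writeNef <- function(data, path, sequence = NULL, media = NULL) {
  stopifnot(is(data, "RdcSet"))
  rec <- data@records
  if (is.null(media)) media <- sort(unique(rec$medium))
  if (!length(media)) media <- 1L
  if (!is.null(sequence)) sequence <- .parseSeq(sequence)
  rname <- function(res, given) {
    out <- if (!is.null(given)) as.character(given) else
      rep(NA_character_, length(res))
    if (!is.null(sequence)) {
      fill <- is.na(out) & res >= 1L & res <= length(sequence)
      out[fill] <- .aa1to3(sequence)[res[fill]]
    }
    out[is.na(out)] <- "."
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("data_rdcfold_rdcs", con)
  for (m in media) {
    r <- rec[rec$medium == m, , drop = FALSE]
    fc <- sprintf("nef_rdc_restraint_list_medium_%d", m)
    writeLines(c(
      sprintf("save_%s", fc),
      "   _nef_rdc_restraint_list.sf_category     nef_rdc_restraint_list",
      sprintf("   _nef_rdc_restraint_list.sf_framecode    %s", fc),
      "   _nef_rdc_restraint_list.restraint_origin  measured",
      "   loop_",
      "      _nef_rdc_restraint.index",
      "      _nef_rdc_restraint.restraint_id",
      "      _nef_rdc_restraint.chain_code_1",
      "      _nef_rdc_restraint.sequence_code_1",
      "      _nef_rdc_restraint.residue_name_1",
      "      _nef_rdc_restraint.atom_name_1",
      "      _nef_rdc_restraint.chain_code_2",
      "      _nef_rdc_restraint.sequence_code_2",
      "      _nef_rdc_restraint.residue_name_2",
      "      _nef_rdc_restraint.atom_name_2",
      "      _nef_rdc_restraint.target_value",
      "      _nef_rdc_restraint.target_value_uncertainty"), con)
    if (nrow(r))
      writeLines(sprintf(
        "      %d %d A %d %s %s A %d %s %s %.6f %.6f",
        seq_len(nrow(r)), seq_len(nrow(r)),
        r$residue_1, rname(r$residue_1, r$resname_1), r$atom_1,
        r$residue_2, rname(r$residue_2, r$resname_2), r$atom_2,
        r$value, r$uncertainty), con)
    writeLines(c("   stop_", "save_", ""), con)
  }
  invisible(path)
}

.LEGACY_TYPES <- data.frame(
  type = c("C-N", "C-H", "N-H", "CA-C", "CA-HA", "C-O"),
  atom_1 = c("C", "C", "N", "CA", "CA", "C"),
  atom_2 = c("N", "H", "H", "C", "HA", "O"),
  offset = c(1L, 1L, 0L, 0L, 0L, 0L),
  stringsAsFactors = FALSE)

#' Read the legacy six-column fixed RDC format
#'
#' Whitespace-separated, one residue per row: six coupling values then six
#' errors (12 columns). Value 999 marks a missing coupling (no record
#' emitted). See the package vignette for the pinned column order.
#'
#' @param path file path.
#' @param medium alignment-medium index assigned to the records.
#' @param sequence optional one-letter sequence (rejects proline N-H rows).
#' @return an \linkS4class{RdcSet}.
#' @export
readLegacyRdc <- function(path, medium = 1L, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nchar(lines) > 0L]
  rows <- list()
  nProlineH <- 0L
  if (!is.null(sequence)) sequence <- .parseSeq(sequence)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\\s+")[[1L]]
    if (length(f) != 12L)
      stop("legacy RDC file ", path, ", line ", i, ": expected 12 columns, ",
           "got ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("legacy RDC file ", path, ", line ", i, ": non-numeric field")
    for (k in seq_len(6L)) {
      if (v[k] == .LEGACY_SENTINEL) next
      ty <- .LEGACY_TYPES[k, ]
      r1 <- i; r2 <- i + ty$offset
      if (!is.null(sequence) &&
          ty$atom_2 == "H" && r2 <= length(sequence) &&
          sequence[r2] == "P") {
        nProlineH <- nProlineH + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        residue_1 = r1, atom_1 = ty$atom_1,
        residue_2 = r2, atom_2 = ty$atom_2,
        medium = as.integer(medium), value = v[k],
        uncertainty = v[k + 6L], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    rows <- list(data.frame(residue_1 = integer(0L), atom_1 = character(0L),
                            residue_2 = integer(0L), atom_2 = character(0L),
                            medium = integer(0L), value = numeric(0L),
                            uncertainty = numeric(0L)))
  if (nProlineH)
    warning("rejected ", nProlineH, " proline amide-H row(s)")
  out <- rdcSet(do.call(rbind, rows))
  attr(out, "nSkipped") <- nProlineH
  out
}

#' Write RDCs in the legacy six-column format
#'
#' Only the six legacy vector types are representable; other records are
#' dropped with a warning. One file per medium.
#'
#' @param data an \linkS4class{RdcSet}.
#' @param path output path.
#' @param medium which medium to write (default 1).
#' @param nResidues number of rows; default: highest residue referenced.
#' @return invisibly, \code{path}.
#' @export
writeLegacyRdc <- function(data, path, medium = 1L, nResidues = NULL) {
  stopifnot(is(data, "RdcSet"))
  rec <- data@records[data@records$medium == medium, , drop = FALSE]
  if (is.null(nResidues))
    nResidues <- max(rec$residue_1, rec$residue_2 - 1L, 1L)
  vals <- matrix(.LEGACY_SENTINEL, nResidues, 6L)
  errs <- matrix(.LEGACY_SENTINEL, nResidues, 6L)
  key <- paste(.LEGACY_TYPES$atom_1, .LEGACY_TYPES$atom_2,
               .LEGACY_TYPES$offset)
  keyR <- paste(.LEGACY_TYPES$atom_2, .LEGACY_TYPES$atom_1,
                -.LEGACY_TYPES$offset)
  nDrop <- 0L
  for (i in seq_len(nrow(rec))) {
    kk <- paste(rec$atom_1[i], rec$atom_2[i],
                rec$residue_2[i] - rec$residue_1[i])
    k <- match(kk, key); rev <- FALSE
    if (is.na(k)) { k <- match(kk, keyR); rev <- TRUE }
    row <- if (!rev) rec$residue_1[i] else rec$residue_2[i]
    if (is.na(k) || row < 1L || row > nResidues) { nDrop <- nDrop + 1L; next }
    vals[row, k] <- rec$value[i]
    errs[row, k] <- rec$uncertainty[i]
  }
  if (nDrop) warning(nDrop, " record(s) not representable in the legacy ",
                     "format were dropped")
  writeLines(apply(cbind(vals, errs), 1L, function(x)
    paste(formatC(x, format = "f", digits = 4L, width = 12L),
          collapse = " ")), path)
  invisible(path)
}

#' Convert a legacy RDC file to NEF
#'
#' @param legacyPaths legacy file paths, one per alignment medium.
#' @param nefPath output NEF path (all media as saveframes of one file).
#' @param sequence optional one-letter sequence for residue names.
#' @return invisibly, \code{nefPath}.
#' @export
convertLegacyToNef <- function(legacyPaths, nefPath, sequence = NULL) {
  sets <- lapply(seq_along(legacyPaths), function(m)
    rdcRecords(readLegacyRdc(legacyPaths[m], medium = m,
                             sequence = sequence)))
  writeNef(rdcSet(do.call(rbind, sets)), nefPath, sequence = sequence,
           media = seq_along(legacyPaths))
  invisible(nefPath)
}

#' Read an INI run configuration
#'
#' Standard INI with \code{#}/\code{;} comments. Sections: \code{[files]}
#' (keys \code{sequence}; \code{rdc} = comma-separated NEF paths (media in
#' order) or \code{rdc_legacy} = comma-separated legacy paths;
#' optional \code{restraints}, \code{out}, \code{pdb});
#' \code{[stage1]} (\code{grid_step}, \code{use_rama});
#' \code{[stage2]} (\code{depth}, \code{decimation} = static|dynamic,
#' \code{tolerance} (percent), \code{static_threshold} (Hz),
#' \code{bucket_width} (degrees), \code{eps_abs} (Hz), \code{seed}).
#' Relative paths are resolved against the config file's directory.
#' Unknown keys warn; missing mandatory keys are errors naming the key.
#'
#' @param path config file path.
#' @return a list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nchar(lines) > 0L]
  sec <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- tolower(gsub("^\\[|\\]$", "", ln))
    } else if (grepl("=", ln, fixed = TRUE)) {
      k <- tolower(trimws(sub("=.*$", "", ln)))
      v <- trimws(sub("^[^=]*=", "", ln))
      kv[[paste0(sec, ".", k)]] <- v
    } else {
      warning("ignoring malformed config line: ", ln)
    }
  }
  known <- c("files.sequence", "files.rdc", "files.rdc_legacy",
             "files.restraints", "files.out", "files.pdb",
             "stage1.grid_step", "stage1.use_rama",
             "stage2.depth", "stage2.decimation", "stage2.tolerance",
             "stage2.static_threshold", "stage2.bucket_width",
             "stage2.eps_abs", "stage2.seed")
  unk <- setdiff(names(kv), known)
  if (length(unk)) warning("unknown config key(s): ",
                           paste(unk, collapse = ", "))
  getv <- function(key, default = NULL, required = FALSE) {
    if (!is.null(kv[[key]])) return(kv[[key]])
    if (required) stop("config is missing mandatory key '", key, "'")
    default
  }
  dir <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^(/|~)", p), p, file.path(dir, p))
  splitPaths <- function(x) if (is.null(x)) NULL else
    rel(trimws(strsplit(x, ",")[[1L]]))
  seqPath <- rel(getv("files.sequence", required = TRUE))
  rdc <- splitPaths(getv("files.rdc"))
  rdcLegacy <- splitPaths(getv("files.rdc_legacy"))
  if (is.null(rdc) && is.null(rdcLegacy))
    stop("config is missing mandatory key 'files.rdc' (or 'files.rdc_legacy')")
  cfg <- list(
    sequenceFile = seqPath,
    rdcFiles = rdc, rdcLegacyFiles = rdcLegacy,
    restraintsFile = if (!is.null(getv("files.restraints")))
      rel(getv("files.restraints")) else NULL,
    outFile = if (!is.null(getv("files.out"))) rel(getv("files.out"))
      else NULL,
    pdbFile = if (!is.null(getv("files.pdb"))) rel(getv("files.pdb"))
      else NULL,
    gridStep = as.numeric(getv("stage1.grid_step", "10")),
    useRama = tolower(getv("stage1.use_rama", "true")) %in%
      c("true", "yes", "1"),
    depth = as.integer(getv("stage2.depth", "1000")),
    decimation = tolower(getv("stage2.decimation", "dynamic")),
    tolerance = as.numeric(getv("stage2.tolerance", "20")),
    staticThreshold = as.numeric(getv("stage2.static_threshold", "Inf")),
    bucketWidth = as.numeric(getv("stage2.bucket_width", "10")),
    epsAbs = as.numeric(getv("stage2.eps_abs", "0.01")),
    seed = as.integer(getv("stage2.seed", "1")))
  if (is.na(cfg$depth) || cfg$depth < 1L)
    stop("config: stage2.depth must be a positive integer")
  if (!cfg$decimation %in% c("static", "dynamic"))
    stop("config: stage2.decimation must be 'static' or 'dynamic'")
  if (cfg$decimation == "dynamic" &&
      (is.na(cfg$tolerance) || cfg$tolerance <= 0))
    stop("config: stage2.tolerance must be > 0 in dynamic mode")
  class(cfg) <- "RunConfig"
  cfg
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  cat("  sequence:", x$sequenceFile, "\n")
  cat("  RDC media:", length(c(x$rdcFiles, x$rdcLegacyFiles)), "file(s)\n")
  cat(sprintf("  stage2: depth %d, %s decimation (tol %.3g%%)\n",
              x$depth, x$decimation, x$tolerance))
  invisible(x)
}

#' Write / read a Stage-II trace (.out) file
#'
#' Line-oriented text, replayable by \code{\link{pdbgenFromOut}}: a
#' \code{STEP} header per elongation step, then one line per surviving
#' fragment: rank, fitness score (Hz) and the torsion sequence as
#' semicolon-separated \code{phi:psi} pairs. Scores are non-decreasing
#' within a step.
#'
#' @param trace list of per-step data.frames (columns rank, score, angles)
#'   as produced by \code{\link{runStage2}}.
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
writeOutTrace <- function(trace, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# stage2 trace: rank score phi1:psi1;phi2:psi2;...", con)
  for (k in seq_along(trace)) {
    st <- trace[[k]]
    writeLines(sprintf("STEP %d", k), con)
    writeLines(sprintf("%d %.9g %s", st$rank, st$score, st$angles), con)
  }
  invisible(path)
}

#' @rdname writeOutTrace
#' @return for \code{readOutTrace}: the trace (list of data.frames).
#' @export
readOutTrace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nchar(trimws(lines)) > 0L]
  trace <- list(); cur <- NULL
  flush <- function() if (!is.null(cur)) trace[[length(trace) + 1L]] <<-
    do.call(rbind.data.frame, cur)
  for (ln in lines) {
    if (grepl("^STEP ", ln)) {
      flush(); cur <- list()
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) != 3L) stop("malformed trace line: ", ln)
      cur[[length(cur) + 1L]] <- data.frame(
        rank = as.integer(f[1L]), score = as.numeric(f[2L]),
        angles = f[3L], stringsAsFactors = FALSE)
    }
  }
  flush()
  trace
}

#' Parse a torsion string of the trace format
#' @param angles string \code{"phi1:psi1;phi2:psi2;..."}.
#' @return n x 2 numeric matrix (phi, psi).
#' @export
parseAngleString <- function(angles) {
  pairs <- strsplit(strsplit(angles, ";")[[1L]], ":")
  m <- t(vapply(pairs, as.numeric, numeric(2L)))
  colnames(m) <- c("phi", "psi")
  m
}

.angleString <- function(tor) {
  paste(sprintf("%.4g:%.4g", tor[, 1L], tor[, 2L]), collapse = ";")
}

#' Read / write per-residue dihedral restraints
#'
#' Plain-text table with a header and columns residue, phi, psi and
#' optionally half_width and step (degrees).
#'
#' @param path file path.
#' @return data.frame with columns residue, phi, psi, half_width, step.
#' @export
readRestraints <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("residue", "phi", "psi")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("restraint table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(d$half_width)) d$half_width <- 25
  if (is.null(d$step)) d$step <- 5
  if (any(d$step <= 0 | d$step > d$half_width))
    stop("restraints must satisfy 0 < step <= half_width")
  d
}

#' @rdname readRestraints
#' @param restraints data.frame as returned by \code{readRestraints} or
#'   \code{\link{predictDihedrals}}.
#' @export
writeRestraints <- function(restraints, path) {
  utils::write.table(restraints, path, row.names = FALSE, quote = FALSE,
                     sep = "\t")
  invisible(path)
}
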
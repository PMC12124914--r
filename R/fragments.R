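# Ingestion of Bismark-style outputs into fragment-level methylation states.
#
# Coordinate conventions used throughout:
#  - read/fragment intervals are 0-based half-open (BED),
#  - Bismark call positions are 1-based and converted on ingestion,
#  - calls on the original-bottom (OB) strand are shifted by -1 so both
#    strands index the C of the CpG dinucleotide on the forward strand.

.open_src <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.open_sink <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read a BED6 file of paired-end bisulfite read intervals
#'
#' Reads the BED dialect produced from Bismark-aligned BAMs: one line per
#' mate with columns chrom, start, end, name, score (ignored), strand.
#' A `/1` or `/2` suffix on the name, when present, is parsed as the mate
#' number and stripped to recover the shared read id.
#'
#' @param path Path to a plain or gzip-compressed BED file. Lines starting
#'   with `#` are ignored.
#' @return A `data.table` with columns `read_id`, `chrom`, `start`, `end`,
#'   `mate` (1, 2, or NA when unlabelled) and `strand`.
#' @export
read_read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 4) stop("read BED needs at least 4 columns (chrom, start, end, name)")
  dt <- dt[, 1:min(6, ncol(dt)), with = FALSE]
  nm <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(dt))]
  data.table::setnames(dt, nm)
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  dt <- dt[!startsWith(as.character(chrom), "#")]
  out <- dt[, .(
    read_id = sub("/[12]$", "", name),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    mate = data.table::fifelse(grepl("/1$", name), 1L,
           data.table::fifelse(grepl("/2$", name), 2L, NA_integer_)),
    strand = as.character(strand)
  )]
  if (any(out$start >= out$end)) stop("read intervals must satisfy start < end")
  out[]
}

#' Merge paired-end read intervals into fragment skeletons
#'
#' Collapses the two mates of each read pair into one fragment interval,
#' the union `[min(start), max(end))` on the shared chromosome. Singleton
#' mates pass through as their own interval. Pairs whose mates map to
#' different chromosomes are rejected and counted.
#'
#' @param reads A data.frame/data.table with columns `read_id`, `chrom`,
#'   `start`, `end` (0-based half-open), e.g. from [read_read_bed()].
#' @return A `data.table` with columns `fragment_id`, `chrom`, `start`,
#'   `end`, `length`, sorted by (chrom, start, end, fragment_id), with
#'   attribute `rejects` giving the number of cross-chromosome pairs
#'   dropped. Conservation: `nrow(result) + rejects` equals the number of
#'   distinct read ids in the input.
#' @export
merge_pe_reads <- function(reads) {
  reads <- data.table::as.data.table(reads)
  req <- c("read_id", "chrom", "start", "end")
  if (!all(req %in% names(reads))) {
    stop("reads need columns: ", paste(req, collapse = ", "))
  }
  if (any(reads$start >= reads$end)) stop("read intervals must satisfy start < end")
  n_per_id <- reads[, .N, by = read_id]
  if (any(n_per_id$N > 2)) {
    stop("more than 2 records for read id(s): ",
         paste(utils::head(n_per_id[N > 2]$read_id, 3), collapse = ", "))
  }
  frag <- reads[, .(
    n_chrom = data.table::uniqueN(chrom),
    chrom = chrom[1L],
    start = min(start),
    end = max(end)
  ), by = read_id]
  rejects <- sum(frag$n_chrom > 1L)
  frag <- frag[n_chrom == 1L, .(fragment_id = read_id, chrom, start, end,
                                length = end - start)]
  data.table::setorder(frag, chrom, start, end, fragment_id)
  data.table::setattr(frag, "rejects", rejects)
  frag[]
}

#' Read a Bismark methylation-extractor CpG call file
#'
#' Parses the tab-delimited dialect of Bismark's `CpG_OT*` / `CpG_OB*`
#' files: read id, call strandness (`+` methylated / `-` unmethylated),
#' chromosome, 1-based position, call symbol (`Z` methylated, `z`
#' unmethylated; other context symbols are dropped). Header lines starting
#' with `#` or `Bismark` are tolerated.
#'
#' Positions are normalized to the 0-based coordinate of the CpG cytosine
#' on the forward strand: 1-based to 0-based conversion for both strands,
#' plus a -1 shift for OB-strand calls (which report the G of the CpG).
#'
#' @param path Plain or gzipped call file.
#' @param strand Either `"OT"` or `"OB"`: which original strand this file
#'   reports (Bismark encodes it in the file name, not the records).
#' @return `data.table` with columns `read_id`, `chrom`, `pos0` (0-based,
#'   strand-normalized) and `state` (1 methylated, 0 unmethylated).
#' @export
read_bismark_calls <- function(path, strand = c("OT", "OB")) {
  strand <- match.arg(strand)
  con <- .open_src(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "Bismark") &
                   nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  pos0 = integer(), state = integer()))
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 2, 3, 5)))
  if (ncol(dt) != 5) stop("Bismark call file must have 5 tab-delimited columns")
  data.table::setnames(dt, c("read_id", "call_strand", "chrom", "pos", "symbol"))
  dt <- dt[dt$symbol %in% c("Z", "z")]  # CpG context only
  shift <- if (strand == "OB") 2L else 1L
  out <- dt[, .(
    read_id = sub("/[12]$", "", read_id),
    chrom = chrom,
    pos0 = as.integer(pos) - shift,
    state = as.integer(symbol == "Z")
  )]
  if (any(out$pos0 < 0)) stop("normalized CpG position < 0; check strand argument")
  out[]
}

#' Merge per-mate CpG calls into per-fragment methylation states
#'
#' Unions the CpG calls of both mates of each fragment. A CpG reported by
#' both mates with the same state appears once; a CpG reported with
#' conflicting states is dropped from the fragment and counted in the
#' `conflicts` attribute (no mate is trusted over the other). Calls whose
#' position falls outside the fragment interval are dropped with a warning.
#'
#' @param calls `data.table` from [read_bismark_calls()] (OT and OB files
#'   may simply be row-bound). Every `read_id` must resolve to a fragment.
#' @param fragments Fragment skeletons from [merge_pe_reads()].
#' @return `data.table` with columns `fragment_id`, `pos0`, `state`,
#'   sorted by fragment and position, with attribute `conflicts` (number
#'   of CpG positions dropped for conflicting duplicate calls). Fragments
#'   with zero calls simply have no rows here; [generate_frag_meth()]
#'   keeps them with an empty state string.
#' @export
merge_cpgs <- function(calls, fragments) {
  calls <- data.table::as.data.table(calls)
  fragments <- data.table::as.data.table(fragments)
  unknown <- setdiff(unique(calls$read_id), fragments$fragment_id)
  if (length(unknown) > 0) {
    stop("methylation calls reference unknown fragment id(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  merged <- fragments[calls, on = c(fragment_id = "read_id"),
                      .(fragment_id, pos0 = i.pos0, state = i.state,
                        start = x.start, end = x.end)]
  oob <- merged$pos0 < merged$start | merged$pos0 >= merged$end
  if (any(oob)) {
    warning(sum(oob), " CpG call(s) outside their fragment interval dropped")
    merged <- merged[!oob]
  }
  merged <- unique(merged[, .(fragment_id, pos0, state)])
  nstates <- merged[, .(k = data.table::uniqueN(state)),
                    by = .(fragment_id, pos0)]
  conflicts <- sum(nstates$k > 1L)
  if (conflicts > 0) {
    merged <- merged[nstates[k == 1L], on = c("fragment_id", "pos0"),
                     nomatch = NULL][, .(fragment_id, pos0, state)]
  }
  data.table::setorder(merged, fragment_id, pos0)
  data.table::setattr(merged, "conflicts", conflicts)
  merged[]
}

#' Build the fragment-level methylation table
#'
#' Joins fragment skeletons with their merged CpG states into the final
#' one-row-per-fragment table. The joint methylation state is serialized
#' in the `methState` column as a string over the alphabet `1` =
#' methylated, `0` = unmethylated, one symbol per CpG in genomic order.
#' Fragments without any CpG call get an empty `methState`.
#'
#' @param fragments Skeletons from [merge_pe_reads()].
#' @param states Per-fragment CpG states from [merge_cpgs()]. State rows
#'   whose fragment id is absent from `fragments` are dropped with a
#'   warning.
#' @return `data.table` with columns `fragment_id`, `chrom`, `start`,
#'   `end`, `length`, `n_cpg`, `methState`, one row per fragment in
#'   `fragments`.
#' @export
generate_frag_meth <- function(fragments, states) {
  fragments <- data.table::as.data.table(fragments)
  states <- data.table::as.data.table(states)
  orphan <- setdiff(unique(states$fragment_id), fragments$fragment_id)
  if (length(orphan) > 0) {
    warning(length(orphan),
            " fragment id(s) present in states but not in fragments; dropped")
    states <- states[!fragment_id %in% orphan]
  }
  enc <- states[order(pos0), .(
    n_cpg = .N,
    methState = paste(state, collapse = "")
  ), by = fragment_id]
  out <- enc[fragments, on = "fragment_id"]
  out[is.na(n_cpg), `:=`(n_cpg = 0L, methState = "")]
  out <- out[, .(fragment_id, chrom, start, end, length, n_cpg, methState)]
  data.table::setorder(out, chrom, start, end, fragment_id)
  out[]
}

#' Write / read the fragment-level methylation table
#'
#' Tab-delimited dialect with a single `#`-prefixed header line and fixed
#' column order `chrom, start, end, length, n_cpg, methState`; gzip
#' compression is selected by a `.gz` suffix. `read_fragment_table()`
#' assigns synthetic row-order fragment ids (`F000001`, ...), since the
#' on-disk dialect does not carry ids.
#'
#' @param fragments Table from [generate_frag_meth()] (extra columns are
#'   ignored on write).
#' @param path Output (input) path, plain or `.gz`.
#' @return `write_fragment_table()` returns `path` invisibly;
#'   `read_fragment_table()` returns a `data.table` in the same layout as
#'   [generate_frag_meth()] output.
#' @export
write_fragment_table <- function(fragments, path) {
  fragments <- data.table::as.data.table(fragments)
  cols <- c("chrom", "start", "end", "length", "n_cpg", "methState")
  if (!all(cols %in% names(fragments))) {
    stop("fragment table needs columns: ", paste(cols, collapse = ", "))
  }
  con <- .open_sink(path)
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(fragments) > 0) {
    utils::write.table(fragments[, cols, with = FALSE], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  con <- .open_src(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    stop("fragment table must start with a '#' header line")
  }
  cols <- c("chrom", "start", "end", "length", "n_cpg", "methState")
  if (length(lines) == 1L) {
    dt <- data.table::data.table(chrom = character(), start = integer(),
                                 end = integer(), length = integer(),
                                 n_cpg = integer(), methState = character())
  } else {
    dt <- data.table::fread(text = lines[-1], header = FALSE, sep = "\t",
                            fill = TRUE,
                            colClasses = list(character = c(1, 6)),
                            col.names = cols)
  }
  dt[is.na(methState), methState := ""]
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            length = as.integer(length), n_cpg = as.integer(n_cpg))]
  bad <- dt$n_cpg != nchar(dt$methState)
  if (any(bad)) stop("n_cpg does not match methState length on ",
                     sum(bad), " row(s)")
  dt[, fragment_id := sprintf("F%06d", .I)]
  data.table::setcolorder(dt, c("fragment_id", "chrom", "start", "end",
                                "length", "n_cpg", "methState"))
  dt[]
}

#' One-call ingestion: BED + call files to fragment table
#'
#' Convenience wrapper running [read_read_bed()], [merge_pe_reads()],
#' [read_bismark_calls()], [merge_cpgs()] and [generate_frag_meth()].
#'
#' @param reads_bed Path to the paired-end read BED file.
#' @param calls_ot,calls_ob Paths to the CpG_OT / CpG_OB call files
#'   (either may be `NULL`).
#' @return Fragment table as from [generate_frag_meth()], with attributes
#'   `rejects` and `conflicts` carried over from the merge steps.
#' @export
ingest_fragments <- function(reads_bed, calls_ot = NULL, calls_ob = NULL) {
  skel <- merge_pe_reads(read_read_bed(reads_bed))
  calls <- data.table::rbindlist(c(
    if (!is.null(calls_ot)) list(read_bismark_calls(calls_ot, "OT")),
    if (!is.null(calls_ob)) list(read_bismark_calls(calls_ob, "OB"))
  ))
  if (nrow(calls) == 0) {
    states <- data.table::data.table(fragment_id = character(),
                                     pos0 = integer(), state = integer())
    data.table::setattr(states, "conflicts", 0L)
  } else {
    states <- merge_cpgs(calls, skel)
  }
  out <- generate_frag_meth(skel, states)
  data.table::setattr(out, "rejects", attr(skel, "rejects"))
  data.table::setattr(out, "conflicts", attr(states, "conflicts"))
  out[]
}

#' Count methylated CpGs in a methState string
#'
#' @param meth_state Character vector of `0`/`1` state strings.
#' @return Integer vector of methylated-CpG counts.
#' @export
count_meth <- function(meth_state) {
  as.integer(nchar(meth_state)) -
    as.integer(nchar(gsub("1", "", meth_state, fixed = TRUE)))
}
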
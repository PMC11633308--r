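# Readers/writers for the external file formats the pipeline consumes.
# All coordinates are 0-based half-open (BED convention) internally; the
# minimal GTF dialect is converted on read.

#' Construct a gene model
#'
#' A gene model holds strand-aware transcript structure: exons, the
#' 5'UTR/CDS/3'UTR partition of exonic space, and the TSS/TTS coordinates
#' implied by the strand. All intervals are 0-based half-open.
#'
#' @param gene_id Gene identifier (unique within an annotation).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`. `"."` is accepted and treated as `"+"`
#'   with a warning, since strand-aware operations cannot sign unstranded
#'   features.
#' @param start,end Gene span in bp, 0-based half-open.
#' @param exons Two-column matrix of exon `(start, end)` intervals, sorted,
#'   non-overlapping.
#' @param utr5,cds,utr3 Optional interval matrices partitioning exonic space;
#'   every interval must be contained in an exon.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, exons,
                       utr5 = NULL, cds = NULL, utr3 = NULL) {
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be '+', '-' or '.': got ", strand)
  }
  if (strand == ".") {
    warning("unstranded gene ", gene_id, " treated as '+'")
    strand <- "+"
  }
  if (start >= end) stop("gene ", gene_id, ": start >= end")
  exons <- as_interval_matrix(exons)
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons")
  if (any(exons[, 1] >= exons[, 2])) {
    stop("gene ", gene_id, ": exon with start >= end")
  }
  if (is.unsorted(exons[, 1], strictly = TRUE) ||
      any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("gene ", gene_id, ": exons must be sorted and non-overlapping")
  }
  if (exons[1, 1] < start || exons[nrow(exons), 2] > end) {
    stop("gene ", gene_id, ": exons outside gene span")
  }
  for (nm in c("utr5", "cds", "utr3")) {
    iv <- as_interval_matrix(get(nm))
    if (nrow(iv) > 0 && !all(intervals_contained(iv, exons))) {
      stop("gene ", gene_id, ": ", nm, " interval outside exons")
    }
    assign(nm, iv)
  }
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    exons = exons, utr5 = utr5, cds = cds, utr3 = utr3,
    tss = if (strand == "+") as.integer(start) else as.integer(end) - 1L,
    tts = if (strand == "+") as.integer(end) - 1L else as.integer(start)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

as_interval_matrix <- function(x) {
  if (is.null(x)) return(matrix(integer(0), ncol = 2))
  x <- matrix(as.integer(x), ncol = 2)
  colnames(x) <- c("start", "end")
  x
}

## TRUE for each interval of `iv` contained in some interval of `container`
intervals_contained <- function(iv, container) {
  vapply(seq_len(nrow(iv)), function(i) {
    any(container[, 1] <= iv[i, 1] & iv[i, 2] <= container[, 2])
  }, logical(1))
}

#' Read a gene annotation
#'
#' Parses either BED12 (thickStart/thickEnd mark the CDS; exon blocks give
#' the transcript structure) or a minimal GTF dialect with `exon` and `CDS`
#' features (1-based closed coordinates, converted to 0-based half-open on
#' read). UTRs are derived from exonic space outside the CDS, assigned
#' 5'/3' by strand.
#'
#' @param path File path.
#' @param dialect `"bed12"` or `"gtf_lite"`.
#' @return A named list of [gene_model()] objects, keyed by `gene_id`.
#' @export
read_annotation <- function(path, dialect = c("bed12", "gtf_lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- read_tsv_lines(path)
  genes <- if (dialect == "bed12") parse_bed12(lines) else parse_gtf_lite(lines)
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(genes) <- ids
  genes
}

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  structure(lines[keep], line_no = which(keep))
}

parse_bed12 <- function(lines) {
  nos <- attr(lines, "line_no")
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      stop("malformed BED12 at line ", nos[i], ": expected 12 fields, got ",
           length(f))
    }
    start <- parse_int(f[2], nos[i]); end <- parse_int(f[3], nos[i])
    thick_s <- parse_int(f[7], nos[i]); thick_e <- parse_int(f[8], nos[i])
    n_blocks <- parse_int(f[10], nos[i])
    sizes <- parse_int_csv(f[11], nos[i])
    starts <- parse_int_csv(f[12], nos[i])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stop("malformed BED12 at line ", nos[i], ": blockCount mismatch")
    }
    if (is.unsorted(starts, strictly = TRUE)) {
      stop("malformed BED12 at line ", nos[i], ": blockStarts out of order")
    }
    exons <- cbind(start + starts, start + starts + sizes)
    parts <- partition_exons_by_cds(exons, thick_s, thick_e, f[6])
    gene_model(gene_id = f[4], chrom = f[1], strand = f[6],
               start = start, end = end, exons = exons,
               utr5 = parts$utr5, cds = parts$cds, utr3 = parts$utr3)
  })
}

## Split exonic space at the CDS bounds; label the flanks 5'/3' by strand.
partition_exons_by_cds <- function(exons, thick_s, thick_e, strand) {
  if (thick_s >= thick_e) {   # non-coding: no CDS, no UTRs
    return(list(utr5 = NULL, cds = NULL, utr3 = NULL))
  }
  clip <- function(lo, hi) {
    s <- pmax(exons[, 1], lo); e <- pmin(exons[, 2], hi)
    m <- cbind(s, e)[s < e, , drop = FALSE]
    if (nrow(m) == 0) NULL else m
  }
  left <- clip(-Inf, thick_s); mid <- clip(thick_s, thick_e)
  right <- clip(thick_e, Inf)
  if (strand == "-") list(utr5 = right, cds = mid, utr3 = left)
  else list(utr5 = left, cds = mid, utr3 = right)
}

parse_gtf_lite <- function(lines) {
  nos <- attr(lines, "line_no")
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("malformed GTF at line ", nos[i])
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", f[9])
    if (identical(gid, f[9])) stop("no gene_id attribute at line ", nos[i])
    list(gene_id = gid, chrom = f[1], feature = f[3],
         start = parse_int(f[4], nos[i]) - 1L,   # 1-based closed -> 0-based half-open
         end = parse_int(f[5], nos[i]), strand = f[7])
  })
  gids <- vapply(rows, `[[`, "", "gene_id")
  lapply(split(rows, factor(gids, levels = unique(gids))), function(rs) {
    feat <- vapply(rs, `[[`, "", "feature")
    iv <- function(which) {
      m <- do.call(rbind, lapply(rs[feat == which], function(r) {
        c(r$start, r$end)
      }))
      if (is.null(m)) NULL else m[order(m[, 1]), , drop = FALSE]
    }
    exons <- iv("exon")
    if (is.null(exons)) stop("gene ", rs[[1]]$gene_id, ": no exon features")
    cds <- iv("CDS")
    parts <- if (is.null(cds)) list(utr5 = NULL, cds = NULL, utr3 = NULL)
             else partition_exons_by_cds(exons, min(cds[, 1]), max(cds[, 2]),
                                         rs[[1]]$strand)
    gene_model(gene_id = rs[[1]]$gene_id, chrom = rs[[1]]$chrom,
               strand = rs[[1]]$strand, start = min(exons[, 1]),
               end = max(exons[, 2]), exons = exons,
               utr5 = parts$utr5, cds = parts$cds, utr3 = parts$utr3)
  })
}

parse_int <- function(x, line) {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) stop("non-integer coordinate '", x, "' at line ", line)
  v
}

parse_int_csv <- function(x, line) {
  parts <- strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]]
  vapply(parts, parse_int, integer(1), line = line, USE.NAMES = FALSE)
}

#' Read eCLIP enriched windows (BED6+2)
#'
#' Expects BED6 columns (`chrom,start,end,name,score,strand`) with two
#' extra columns, `odds_ratio` and `fdr`, as emitted by Skipper-style eCLIP
#' window callers. The `name` column carries the assigned gene id. Further
#' extra columns are carried through untouched.
#'
#' @param path File path.
#' @return A data frame with one row per window; class `enriched_windows`.
#' @export
read_windows <- function(path) {
  df <- read_bed_family(path, min_cols = 8,
                        col_names = c("chrom", "start", "end", "gene_id",
                                      "score", "strand", "odds_ratio", "fdr"),
                        numeric_cols = c("odds_ratio", "fdr"))
  if (nrow(df) > 0) {
    if (any(df$fdr < 0 | df$fdr > 1)) stop("fdr outside [0,1] in ", path)
    if (any(df$odds_ratio < 0)) stop("negative odds_ratio in ", path)
  }
  class(df) <- c("enriched_windows", "data.frame")
  df
}

#' Write eCLIP enriched windows
#' @param windows Data frame from [read_windows()] or the simulator.
#' @param path Output path.
#' @export
write_windows <- function(windows, path) {
  write_bed_family(windows, path,
                   c("chrom", "start", "end", "gene_id", "score", "strand",
                     "odds_ratio", "fdr"))
}

#' Read Cut&Run peaks (narrowPeak)
#'
#' Standard 10-column narrowPeak. A summit (`peak`) value of -1 is recorded
#' as `NA` per the format convention. Peaks are not gene-assigned on read;
#' see [assign_nearest_gene()].
#'
#' @param path File path.
#' @return A data frame of peaks; class `dna_peaks`.
#' @export
read_narrowpeak <- function(path) {
  df <- read_bed_family(path, min_cols = 10,
                        col_names = c("chrom", "start", "end", "name", "score",
                                      "strand", "signal", "pvalue", "qvalue",
                                      "summit_offset"),
                        numeric_cols = c("signal", "pvalue", "qvalue"))
  if (nrow(df) > 0) {
    df$summit_offset <- ifelse(df$summit_offset == -1L, NA_integer_,
                               df$summit_offset)
    bad <- !is.na(df$summit_offset) &
      (df$summit_offset < 0 | df$summit_offset >= df$end - df$start)
    if (any(bad)) stop("summit offset outside peak in ", path)
  }
  class(df) <- c("dna_peaks", "data.frame")
  df
}

#' Write Cut&Run peaks (narrowPeak)
#' @param peaks Data frame from [read_narrowpeak()] or the simulator.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks$summit_offset <- ifelse(is.na(peaks$summit_offset), -1L,
                                peaks$summit_offset)
  write_bed_family(peaks, path,
                   c("chrom", "start", "end", "name", "score", "strand",
                     "signal", "pvalue", "qvalue", "summit_offset"))
}

read_bed_family <- function(path, min_cols, col_names, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- read_tsv_lines(path)
  if (length(lines) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(col_names)),
                                 col_names))
    for (cc in c("start", "end", numeric_cols)) df[[cc]] <- numeric(0)
    return(df)
  }
  nos <- attr(lines, "line_no")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    stop("line ", nos[which(nf < min_cols)[1]], ": expected >= ", min_cols,
         " fields, got ", nf[which(nf < min_cols)[1]])
  }
  nmax <- max(nf)
  mat <- t(vapply(fields, function(f) c(f, rep(NA_character_, nmax - length(f))),
                  character(nmax)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  extra_n <- nmax - length(col_names)
  names(df) <- c(col_names, if (extra_n > 0) paste0("extra", seq_len(extra_n)))
  for (cc in c("start", "end")) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v)) {
      stop("non-integer coordinate at line ", nos[which(is.na(v))[1]])
    }
    df[[cc]] <- v
  }
  if (any(df$end <= df$start)) stop("interval with end <= start in ", path)
  if ("summit_offset" %in% names(df)) {
    df$summit_offset <- suppressWarnings(as.integer(df$summit_offset))
  }
  if ("score" %in% names(df)) {
    df$score <- suppressWarnings(as.numeric(df$score))
  }
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) stop("unparseable numeric in column ", cc)
    df[[cc]] <- v
  }
  if ("strand" %in% names(df) && any(!df$strand %in% c("+", "-", "."))) {
    stop("missing or invalid strand field")
  }
  df
}

write_bed_family <- function(df, path, col_names) {
  extra <- grep("^extra", names(df), value = TRUE)
  cols <- c(col_names, extra)
  out <- vapply(cols, function(cc) as.character(df[[cc]]), character(nrow(df)))
  if (nrow(df) == 1) out <- matrix(out, nrow = 1)
  writeLines(apply(matrix(out, nrow = nrow(df)), 1, paste, collapse = "\t"),
             path)
  invisible(path)
}

#' Write gene models as BED12
#' @param genes Named list of [gene_model()] objects.
#' @param path Output path.
#' @export
write_annotation_bed12 <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    cds <- g$cds
    thick <- if (is.null(cds) || nrow(cds) == 0) c(g$start, g$start)
             else c(min(cds[, 1]), max(cds[, 2]))
    sizes <- g$exons[, 2] - g$exons[, 1]
    starts <- g$exons[, 1] - g$start
    paste(g$chrom, g$start, g$end, g$gene_id, 0, g$strand,
          thick[1], thick[2], "0,0,0", nrow(g$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- generic typed TSV ------------------------------------------------------

#' Read a typed TSV table against a column schema
#'
#' Reads a tab-separated file with a header (lines starting with `#`
#' ignored) and maps/validates columns per a schema. Canned schemas for the
#' pipeline's table families are available from [table_schema()].
#'
#' @param path File path.
#' @param schema A schema from [table_schema()], or a named list of
#'   `list(from = <column in file>, type = "character"|"numeric"|"integer",
#'   required = TRUE)` entries keyed by output field name.
#' @return Data frame with schema fields first (renamed/typed) and any
#'   unknown columns preserved after them.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1) schema <- table_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  out <- list()
  for (field in names(schema)) {
    sc <- schema[[field]]
    if (!sc$from %in% names(df)) {
      if (isTRUE(sc$required)) stop("missing required column '", sc$from,
                                    "' in ", path)
      out[[field]] <- rep(NA, nrow(df))
      next
    }
    v <- df[[sc$from]]
    if (sc$type %in% c("numeric", "integer")) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA" & v != "")
      if (length(bad)) stop("unparseable numeric in column '", sc$from,
                            "' at row ", bad[1])
      conv[v %in% c("NA", "")] <- NA
      v <- if (sc$type == "integer") as.integer(conv) else conv
    }
    out[[field]] <- v
  }
  known <- vapply(schema, `[[`, "", "from")
  extra <- df[, setdiff(names(df), known), drop = FALSE]
  res <- cbind(as.data.frame(out, stringsAsFactors = FALSE,
                             check.names = FALSE), extra)
  if (nrow(df) == 0) {
    res <- as.data.frame(lapply(res, function(x) x[0]), check.names = FALSE)
  }
  res
}

#' Canned table schemas
#'
#' @param name One of `"deseq2"`, `"rmats_se"`, `"apa"`, `"slam"`, `"epr"`,
#'   `"tethering"`, `"event_counts"`, `"protein_tracks"`, `"domains"`.
#' @return A schema list usable with [read_table()].
#' @export
table_schema <- function(name) {
  col <- function(from, type = "numeric", required = TRUE) {
    list(from = from, type = type, required = required)
  }
  switch(name,
    deseq2 = list(gene_id = col("gene_id", "character"),
                  log2fc = col("log2FoldChange"),
                  fdr = col("padj")),
    rmats_se = list(event_id = col("event_id", "character"),
                    gene_id = col("gene_id", "character"),
                    event_type = col("event_type", "character"),
                    junction_starts = col("junction_starts", "character"),
                    delta_psi = col("delta_psi"),
                    fdr = col("fdr")),
    apa = list(gene_id = col("gene_id", "character"),
               delta_psi = col("delta_psi"),
               fdr = col("fdr")),
    slam = list(gene_id = col("gene_id", "character"),
                condition = col("condition", "character"),
                timepoint_h = col("timepoint_h"),
                replicate = col("replicate", "integer"),
                tc_conversions = col("tc_conversions"),
                library_total = col("library_total")),
    epr = list(gene_id = col("gene_id", "character"),
               sample = col("sample", "character"),
               edits = col("edits"),
               exon_reads = col("exon_reads")),
    tethering = list(construct_id = col("construct_id", "character"),
                     replicate = col("replicate", "integer"),
                     firefly = col("firefly"),
                     renilla = col("renilla"),
                     reporter = col("reporter", "character", required = FALSE)),
    event_counts = list(zfp_id = col("zfp_id", "character"),
                        batch = col("batch", "character"),
                        degs = col("degs", "integer"),
                        ases = col("ases", "integer"),
                        apaes = col("apaes", "integer")),
    protein_tracks = list(protein_id = col("protein_id", "character"),
                          position = col("position", "integer"),
                          occlusion_z = col("occlusion_z"),
                          disorder_score = col("disorder_score")),
    domains = list(protein_id = col("protein_id", "character"),
                   class = col("class", "character"),
                   start = col("start", "integer"),
                   end = col("end", "integer")),
    stop("unknown schema: ", name)
  )
}

#' Write a data frame as the package's TSV dialect
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Parse an rMATS-style splice event table
#'
#' Wraps [read_table()] with the `rmats_se` schema and splits the
#' comma-separated junction coordinate column into integer vectors.
#'
#' @param path File path.
#' @return Data frame with a `junction_coords` list-column.
#' @export
read_splice_events <- function(path) {
  df <- read_table(path, "rmats_se")
  df$junction_coords <- lapply(strsplit(df$junction_starts, ","), function(x) {
    as.integer(x)
  })
  bad <- !df$event_type %in% c("SE", "A5SS", "A3SS", "MXE", "RI")
  if (any(bad)) stop("unknown event_type: ", df$event_type[which(bad)[1]])
  if (any(abs(df$delta_psi) > 1, na.rm = TRUE)) stop("|delta_psi| > 1")
  df
}
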
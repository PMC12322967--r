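# Reading and writing ClinVar VCF snapshots restricted to a gene panel.
#
# The reader is deliberately a thin line-oriented parser rather than a full
# VCF stack: the CLNSIG/CLNREVSTAT strings must be preserved byte-for-byte
# for auditable provenance, and general-purpose VCF readers re-tokenize
# comma-separated INFO values (ClinVar significance strings legitimately
# contain commas, e.g. "Pathogenic,_low_penetrance").

#' Construct a snapshot table
#'
#' A snapshot table holds the panel-restricted records of one dated ClinVar
#' pull: a `data.table` keyed by the exact (chrom, pos, ref, alt) variant
#' identity, with verbatim significance and review-status strings.
#'
#' @param records `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genes` (comma-joined symbols), `clnsig_raw`, `revstat_raw`.
#' @param gene_panel Character vector of panel gene symbols.
#' @param label Snapshot identifier (typically the pull date).
#' @return An object of class `snapshot_table`: a list with elements
#'   `label`, `records` (sorted `data.table` with a `vid` identity column)
#'   and `gene_panel`.
#' @export
snapshot_table <- function(records, gene_panel, label = "snapshot") {
  rec <- data.table::as.data.table(records)
  needed <- c("chrom", "pos", "ref", "alt", "genes", "clnsig_raw", "revstat_raw")
  missing_cols <- setdiff(needed, names(rec))
  abort_if(length(missing_cols) > 0,
           "snapshot records missing columns: ", paste(missing_cols, collapse = ", "))
  rec <- rec[, needed, with = FALSE]
  rec[, chrom := as.character(chrom)]
  rec[, pos := as.integer(pos)]
  abort_if(any(is.na(rec$pos)) || any(rec$pos < 1L), "positions must be integers >= 1")
  abort_if(any(rec$ref == rec$alt), "ref and alt alleles must differ")
  gene_panel <- sort(unique(as.character(gene_panel)))
  in_panel <- vapply(split_genes(rec$genes), function(g) any(g %in% gene_panel), logical(1))
  abort_if(nrow(rec) > 0 && !all(in_panel),
           "every record must list at least one panel gene")
  rec[, vid := variant_id(chrom, pos, ref, alt)]
  abort_if(anyDuplicated(rec$vid) > 0, "duplicate variant keys in snapshot")
  rec <- rec[variant_order(chrom, pos, ref, alt)]
  structure(list(label = label, records = rec[], gene_panel = gene_panel),
            class = "snapshot_table")
}

#' @export
print.snapshot_table <- function(x, ...) {
  cat(sprintf("<snapshot_table '%s': %d records, %d panel genes>\n",
              x$label, nrow(x$records), length(x$gene_panel)))
  invisible(x)
}

# Extract one INFO key verbatim from raw INFO strings; "" where absent.
info_field <- function(info, key) {
  has <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
  out <- character(length(info))
  out[has] <- sub(paste0("^(?:.*;)?", key, "=([^;]*).*$"), "\\1", info[has], perl = TRUE)
  out
}

#' Read a ClinVar VCF snapshot restricted to a gene panel
#'
#' Parses a ClinVar-dialect VCF (plain or gzip), keeping one record per data
#' line whose ALT is a single concrete allele and whose GENEINFO lists at
#' least one panel gene. `CLNSIG` and `CLNREVSTAT` are stored verbatim;
#' missing keys become the empty string. Multi-allelic lines are a fatal
#' error (ClinVar emits one variation per line; a multi-allelic line
#' signals a wrong input file). Lines with ALT "." or a symbolic/breakend
#' allele are silently dropped. "chr" prefixes are stripped.
#'
#' @param path Path to the VCF (`.vcf` or `.vcf.gz`).
#' @param gene_panel Panel gene symbols; defaults to [banner_gene_panel()].
#' @param label Snapshot label; defaults to the file name.
#' @return A [snapshot_table()].
#' @export
read_clinvar_vcf <- function(path, gene_panel = banner_gene_panel(),
                             label = basename(path)) {
  abort_if(!file.exists(path), "ClinVar VCF not found: ", path)
  con <- file(path, "rt")  # file() transparently decompresses gzip
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_meta <- startsWith(lines, "##")
  is_head <- startsWith(lines, "#") & !is_meta
  header <- lines[is_meta]
  for (k in c("CLNSIG", "CLNREVSTAT", "GENEINFO")) {
    abort_if(!any(grepl(paste0("##INFO=<ID=", k, ","), header, fixed = TRUE)),
             path, ": VCF header lacks INFO key ", k)
  }
  abort_if(!any(is_head), path, ": missing #CHROM header line")
  data <- lines[!is_meta & !is_head & nzchar(lines)]
  if (length(data) == 0) {
    return(snapshot_table(
      data.table::data.table(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             genes = character(), clnsig_raw = character(),
                             revstat_raw = character()),
      gene_panel, label))
  }
  fields <- data.table::tstrsplit(data, "\t", fixed = TRUE)
  abort_if(length(fields) < 8, path, ": data lines have fewer than 8 VCF columns")
  chrom <- sub("^chr", "", fields[[1]])
  pos_raw <- fields[[2]]
  ref <- toupper(fields[[4]])
  alt_raw <- fields[[5]]
  info <- fields[[8]]

  multi <- grepl(",", alt_raw, fixed = TRUE)
  abort_if(any(multi),
           path, ": multi-allelic ALT at line(s) ",
           paste(utils::head(which(multi), 3), collapse = ", "),
           " (of retained data lines); ClinVar VCFs carry one variation per line")
  keep <- alt_raw != "." & !grepl("[<>\\[\\]*]", alt_raw, perl = TRUE)
  chrom <- chrom[keep]; pos_raw <- pos_raw[keep]; ref <- ref[keep]
  alt <- toupper(alt_raw[keep]); info <- info[keep]

  pos <- suppressWarnings(as.integer(pos_raw))
  bad_pos <- is.na(pos) | pos < 1L
  abort_if(any(bad_pos), path, ": malformed POS '",
           pos_raw[which(bad_pos)[1]], "'")
  bad_allele <- !grepl("^[ACGTN]+$", ref) | !grepl("^[ACGTN]+$", alt)
  abort_if(any(bad_allele), path, ": malformed REF/ALT allele '",
           ref[which(bad_allele)[1]], "/", alt[which(bad_allele)[1]], "'")

  geneinfo <- info_field(info, "GENEINFO")
  genes_list <- lapply(strsplit(geneinfo, "|", fixed = TRUE), function(entries) {
    unique(sub(":.*$", "", entries[nzchar(entries)]))
  })
  in_panel <- vapply(genes_list, function(g) any(g %in% gene_panel), logical(1))

  rec <- data.table::data.table(
    chrom = chrom[in_panel],
    pos = pos[in_panel],
    ref = ref[in_panel],
    alt = alt[in_panel],
    genes = vapply(genes_list[in_panel], paste, character(1), collapse = ","),
    clnsig_raw = info_field(info[in_panel], "CLNSIG"),
    revstat_raw = info_field(info[in_panel], "CLNREVSTAT")
  )
  dup <- duplicated(variant_id(rec$chrom, rec$pos, rec$ref, rec$alt))
  if (any(dup)) {
    warning(path, ": ", sum(dup), " duplicate variant key(s) dropped (kept first)")
    rec <- rec[!dup]
  }
  snapshot_table(rec, gene_panel, label)
}

#' Write a snapshot table to TSV
#'
#' One row per record, columns `chrom`, `pos`, `ref`, `alt`, `genes`
#' (comma-joined), `clnsig_raw`, `revstat_raw`, in variant-key order.
#' Round-trips losslessly through [read_snapshot_tsv()].
#'
#' @param snapshot A [snapshot_table()].
#' @param path Output file path.
#' @export
write_snapshot_tsv <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "snapshot_table"))
  cols <- c("chrom", "pos", "ref", "alt", "genes", "clnsig_raw", "revstat_raw")
  data.table::fwrite(snapshot$records[, cols, with = FALSE], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a snapshot table written by [write_snapshot_tsv()]
#'
#' @inheritParams read_clinvar_vcf
#' @export
read_snapshot_tsv <- function(path, gene_panel = banner_gene_panel(),
                              label = basename(path)) {
  abort_if(!file.exists(path), "snapshot TSV not found: ", path)
  rec <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("chrom", "ref", "alt", "genes", "clnsig_raw", "revstat_raw"),
    integer = "pos"))
  rec[is.na(clnsig_raw), clnsig_raw := ""]
  rec[is.na(revstat_raw), revstat_raw := ""]
  snapshot_table(rec, gene_panel, label)
}

#' Write a snapshot table as a ClinVar-dialect VCF
#'
#' Emits a syntactically valid VCF with `GENEINFO`, `CLNSIG` and
#' `CLNREVSTAT` INFO keys, suitable for re-reading with
#' [read_clinvar_vcf()]. Used by the synthetic-snapshot generator.
#'
#' @param snapshot A [snapshot_table()].
#' @param path Output `.vcf` path.
#' @export
write_clinvar_vcf <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "snapshot_table"))
  rec <- snapshot$records
  header <- c(
    "##fileformat=VCFv4.1",
    sprintf("##fileDate=%s", snapshot$label),
    "##INFO=<ID=GENEINFO,Number=1,Type=String,Description=\"Gene(s) for the variant reported as gene symbol:gene id\">",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance for this single variant\">",
    "##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description=\"ClinVar review status for the Variation ID\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  geneinfo <- vapply(split_genes(rec$genes), function(g) {
    paste(sprintf("%s:%d", g, abs(match(g, banner_gene_panel(), nomatch = 0L)) + 1000L),
          collapse = "|")
  }, character(1))
  body <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t.\tGENEINFO=%s;CLNSIG=%s;CLNREVSTAT=%s",
                  rec$chrom, rec$pos, seq_len(nrow(rec)), rec$ref, rec$alt,
                  geneinfo, rec$clnsig_raw, rec$revstat_raw)
  writeLines(c(header, body), path)
  invisible(path)
}
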
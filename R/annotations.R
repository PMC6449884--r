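#' Parse gene and disease phenotype annotations
#'
#' Reads the two standard annotation dialects — a `genes_to_phenotype.txt`
#' style TSV (gene symbol + phenotype term id) and a `phenotype.hpoa` style
#' TSV (disease id + phenotype term id + optional frequency) — and validates
#' them against an ontology.  Rows whose term id (after alt-id resolution)
#' is not in the ontology are dropped and counted.
#'
#' Frequency cells are parsed as: `n/m` ratios, percentage strings, bare
#' numbers in \[0,1\], or HPO frequency-modifier term ids mapped to midpoint
#' probabilities (Obligate 1.0, Very frequent 0.895, Frequent 0.545,
#' Occasional 0.17, Very rare 0.025, Excluded 0.0).  A missing frequency
#' means 1.0.
#'
#' @param gene_path Path to the gene-to-phenotype TSV.
#' @param disease_path Path to the disease-to-phenotype TSV.
#' @param ontology A `pheno_ontology`.
#' @return A `pheno_corpus`: list with `gene_to_terms` and
#'   `disease_to_terms` (named lists of term-id character vectors),
#'   `frequency` (tibble `disease_id`, `term_id`, `frequency`), and
#'   `dropped` (named integer, rows dropped per file).
#' @export
parse_annotations <- function(gene_path, disease_path, ontology) {
  g <- read_annotation_tsv(gene_path, kind = "gene")
  d <- read_annotation_tsv(disease_path, kind = "disease")

  fix <- function(df) {
    hit <- df$term_id %in% names(ontology$alt_ids)
    df$term_id[hit] <- unname(ontology$alt_ids[df$term_id[hit]])
    known <- df$term_id %in% ontology$terms$id
    list(df = df[known, , drop = FALSE], dropped = sum(!known))
  }
  gf <- fix(g); df <- fix(d)
  dropped <- c(gene = gf$dropped, disease = df$dropped)
  if (sum(dropped) > 0)
    message("dropped ", dropped[["gene"]], " gene and ",
            dropped[["disease"]], " disease annotation rows with term ids ",
            "absent from the ontology")
  if (nrow(gf$df) == 0L) stop("gene annotation corpus is empty", call. = FALSE)
  if (nrow(df$df) == 0L)
    stop("disease annotation corpus is empty", call. = FALSE)

  freq <- tibble::tibble(
    disease_id = df$df$unit,
    term_id = df$df$term_id,
    frequency = vapply(df$df$frequency, parse_frequency, numeric(1))
  )
  freq <- dplyr::summarise(dplyr::group_by(freq, .data$disease_id,
                                           .data$term_id),
                           frequency = max(.data$frequency), .groups = "drop")

  new_corpus(
    gene_to_terms = lapply(split(gf$df$term_id, gf$df$unit), unique),
    disease_to_terms = lapply(split(df$df$term_id, df$df$unit), unique),
    frequency = freq, dropped = dropped
  )
}

#' @rdname parse_annotations
#' @param gene_to_terms Named list: gene symbol -> character vector of terms.
#' @param disease_to_terms Named list: disease id -> character vector.
#' @param frequency Tibble `disease_id`, `term_id`, `frequency` in \[0,1\];
#'   pairs absent from the table default to frequency 1.
#' @param dropped Named integer bookkeeping (defaults to zeros).
#' @export
new_corpus <- function(gene_to_terms, disease_to_terms,
                       frequency = NULL,
                       dropped = c(gene = 0L, disease = 0L)) {
  if (is.null(frequency))
    frequency <- tibble::tibble(disease_id = character(),
                                term_id = character(),
                                frequency = numeric())
  stopifnot(all(frequency$frequency >= 0 & frequency$frequency <= 1))
  structure(list(gene_to_terms = gene_to_terms,
                 disease_to_terms = disease_to_terms,
                 frequency = tibble::as_tibble(frequency),
                 dropped = dropped),
            class = "pheno_corpus")
}

#' @export
print.pheno_corpus <- function(x, ...) {
  cat("<pheno_corpus> ", length(x$gene_to_terms), " genes (",
      sum(lengths(x$gene_to_terms)), " annotations), ",
      length(x$disease_to_terms), " diseases (",
      sum(lengths(x$disease_to_terms)), " annotations)\n", sep = "")
  invisible(x)
}

# flexible TSV reader: header may start with '#'; columns found by name
# (preferred) or by content (term column = entries matching PREFIX:digits).
read_annotation_tsv <- function(path, kind = c("gene", "disease")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # '#Format:' style preamble comments are skipped; a '#'-prefixed header
  # immediately above the data is kept as the header
  is_comment <- startsWith(lines, "#")
  header_idx <- if (any(!is_comment)) {
    first_data <- which(!is_comment)[1]
    if (first_data > 1L && grepl("\t", lines[first_data - 1L]))
      first_data - 1L else first_data
  } else stop("no data rows in ", path, call. = FALSE)
  header_has_ids <- grepl("HP:\\d", lines[header_idx]) ||
    grepl("^[^\t]*:\\d{4}", lines[header_idx])
  body <- lines[seq(header_idx, length(lines))]
  body <- body[!startsWith(body, "#") | seq_along(body) == 1L]
  df <- utils::read.delim(text = body, header = !header_has_ids,
                          sep = "\t", quote = "", colClasses = "character",
                          check.names = FALSE)
  names(df) <- sub("^#", "", trimws(tolower(names(df))))

  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit)) hit[1] else NA_character_
  }
  term_col <- pick(c("hpo_id", "hpo-term-id", "hpo term id", "term_id"))
  if (is.na(term_col)) {
    looks <- vapply(df, function(col)
      mean(grepl("^[A-Za-z]+:\\d+$", col)) > 0.5, logical(1))
    # frequency cells can also be HP ids; take the first matching column
    if (!any(looks))
      stop("cannot locate the phenotype term id column in ", path,
           call. = FALSE)
    term_col <- names(df)[which(looks)[if (kind == "disease") 2 else 1]]
    if (is.na(term_col)) term_col <- names(df)[which(looks)[1]]
  }
  unit_col <- if (kind == "gene") {
    pick(c("gene_symbol", "gene-symbol", "entrez-gene-symbol", "gene"))
  } else {
    pick(c("database_id", "databaseid", "disease_id", "diseaseid"))
  }
  if (is.na(unit_col)) {
    cand <- setdiff(names(df), term_col)
    if (!length(cand))
      stop("missing mandatory ", kind, " id column in ", path, call. = FALSE)
    unit_col <- cand[1]
  }
  freq_col <- pick(c("frequency", "freq"))
  out <- tibble::tibble(
    unit = df[[unit_col]],
    term_id = df[[term_col]],
    frequency = if (!is.na(freq_col)) df[[freq_col]] else
      rep(NA_character_, nrow(df))
  )
  out[nzchar(out$unit) & nzchar(out$term_id), , drop = FALSE]
}

hpo_frequency_map <- c(
  "HP:0040280" = 1.0,    # Obligate
  "HP:0040281" = 0.895,  # Very frequent
  "HP:0040282" = 0.545,  # Frequent
  "HP:0040283" = 0.17,   # Occasional
  "HP:0040284" = 0.025,  # Very rare
  "HP:0040285" = 0.0     # Excluded
)

#' Parse a frequency/penetrance annotation cell
#'
#' @param x A single frequency string (may be `NA` or empty).
#' @return A probability in \[0,1\]; missing input gives 1.
#' @export
parse_frequency <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(1.0)
  x <- trimws(x)
  if (x %in% names(hpo_frequency_map)) return(unname(hpo_frequency_map[x]))
  if (grepl("^\\d+\\s*/\\s*\\d+$", x)) {
    parts <- as.numeric(strsplit(x, "/")[[1]])
    if (parts[2] == 0) return(1.0)
    return(min(1, parts[1] / parts[2]))
  }
  if (grepl("%$", x)) {
    v <- suppressWarnings(as.numeric(sub("%$", "", x)))
    if (!is.na(v)) return(min(1, max(0, v / 100)))
  }
  v <- suppressWarnings(as.numeric(x))
  if (!is.na(v) && v >= 0 && v <= 1) return(v)
  warning("unparseable frequency '", x, "'; using 1.0", call. = FALSE)
  1.0
}

#' Write annotation tables in the standard TSV dialects
#'
#' `write_gene_annotations()` emits a `genes_to_phenotype.txt`-style file
#' (columns `gene_symbol`, `hpo_id`); `write_disease_annotations()` emits a
#' `phenotype.hpoa`-style file (columns `database_id`, `hpo_id`,
#' `frequency`).  Both round-trip through [parse_annotations()].
#'
#' @param corpus A `pheno_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(corpus, path) {
  df <- tibble::tibble(
    gene_symbol = rep(names(corpus$gene_to_terms),
                      lengths(corpus$gene_to_terms)),
    hpo_id = unlist(corpus$gene_to_terms, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_annotations
#' @export
write_disease_annotations <- function(corpus, path) {
  df <- tibble::tibble(
    database_id = rep(names(corpus$disease_to_terms),
                      lengths(corpus$disease_to_terms)),
    hpo_id = unlist(corpus$disease_to_terms, use.names = FALSE)
  )
  key <- paste(df$database_id, df$hpo_id)
  fr <- corpus$frequency
  fmap <- stats::setNames(fr$frequency, paste(fr$disease_id, fr$term_id))
  df$frequency <- ifelse(key %in% names(fmap),
                         format(fmap[key], trim = TRUE), "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# frequency lookup with default 1.0 for unlisted pairs
disease_frequencies <- function(corpus, disease) {
  terms <- corpus$disease_to_terms[[disease]]
  if (is.null(terms))
    stop("unknown disease id: ", disease, call. = FALSE)
  fr <- corpus$frequency[corpus$frequency$disease_id == disease, ,
                         drop = FALSE]
  out <- stats::setNames(rep(1.0, length(terms)), terms)
  hit <- intersect(fr$term_id, terms)
  out[hit] <- fr$frequency[match(hit, fr$term_id)]
  out
}
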
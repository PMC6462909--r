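#' Load a two-column target map from TSV
#'
#' Reads a `source<TAB>target` file (optional `source  target` header),
#' trimming identifier whitespace, preserving case, and collapsing duplicate
#' pairs with a warning.
#'
#' @param path Path to the TSV file.
#' @param source_type Either `"lncRNA"` or `"miRNA"`; stored as an attribute.
#' @return A `target_map`: data frame with columns `source` and `target`,
#'   attribute `source_type`.
#' @export
load_target_map <- function(path, source_type = c("lncRNA", "miRNA")) {
  source_type <- match.arg(source_type)
  if (!file.exists(path))
    stop_lncnet("lncnet_io_error", "target map file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("empty target map: %s", path))
    return(target_map(data.frame(source = character(0), target = character(0)),
                      source_type))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop_lncnet("lncnet_parse_error", "malformed target-map line %d in %s (expected 2 columns)",
                bad[1], path)
  m <- do.call(rbind, fields)
  df <- data.frame(source = trimws(m[, 1]), target = trimws(m[, 2]),
                   stringsAsFactors = FALSE)
  if (identical(unname(tolower(as.character(df[1, ]))), c("source", "target")))
    df <- df[-1, , drop = FALSE]
  ndup <- sum(duplicated(df))
  if (ndup > 0) warning(sprintf("%d duplicate pair(s) collapsed in %s", ndup, path))
  df <- unique(df)
  rownames(df) <- NULL
  target_map(df, source_type)
}

#' Construct a target map from a data frame
#' @param pairs Data frame with columns `source` and `target`.
#' @param source_type `"lncRNA"` or `"miRNA"`.
#' @return A validated `target_map`.
#' @export
target_map <- function(pairs, source_type = c("lncRNA", "miRNA")) {
  source_type <- match.arg(source_type)
  stopifnot(is.data.frame(pairs), all(c("source", "target") %in% names(pairs)))
  pairs <- unique(data.frame(source = trimws(as.character(pairs$source)),
                             target = trimws(as.character(pairs$target)),
                             stringsAsFactors = FALSE))
  if (nrow(pairs) && any(!nzchar(pairs$source) | !nzchar(pairs$target)))
    stop_lncnet("lncnet_invalid_input", "target-map identifiers must be non-empty")
  rownames(pairs) <- NULL
  structure(pairs, source_type = source_type,
            class = c("target_map", "data.frame"))
}

#' Targets of one source in a map
#' @param map A `target_map`.
#' @param source_id Source identifier.
#' @return Character vector of targets (possibly empty).
#' @export
map_targets <- function(map, source_id) {
  sort(unique(map$target[map$source == source_id]))
}

#' Build per-miRNA profiles of DEG targets
#'
#' For each miRNA annotated as an lncRNA target, intersects its gene targets
#' with the DEG set. miRNAs absent from the miRNA->gene map are reported as
#' unmapped; miRNAs whose DEG-target intersection is empty are dropped from the
#' returned profiles but counted (the published worked example retained 47 of
#' 56). Conservation: `nrow(profiles) + length(dropped) + length(unmapped) ==
#' length(lnc_mirnas)`.
#'
#' @param lnc_mirnas Character vector of miRNA identifiers (the lncRNA's
#'   annotated miRNA targets).
#' @param mirna_gene_map A `target_map` with miRNA sources and gene targets.
#' @param deg_genes Character vector of DEG identifiers (may be empty).
#' @return A `mirna_profiles` data frame sorted by `mirna_id`, with columns
#'   `mirna_id`, `n_all_targets`, `n_deg_targets`, `selected` and list-columns
#'   `all_targets`, `deg_targets`, `module_hits`; attributes `dropped` and
#'   `unmapped` hold the excluded miRNA identifiers.
#' @export
build_profiles <- function(lnc_mirnas, mirna_gene_map, deg_genes) {
  lnc_mirnas <- sort(unique(as.character(lnc_mirnas)))
  deg_genes <- unique(as.character(deg_genes))
  mapped <- unique(mirna_gene_map$source)
  unmapped <- setdiff(lnc_mirnas, mapped)
  present <- intersect(lnc_mirnas, mapped)

  all_t <- lapply(present, function(mi) map_targets(mirna_gene_map, mi))
  deg_t <- lapply(all_t, function(tg) sort(intersect(tg, deg_genes)))
  keep <- lengths(deg_t) > 0
  dropped <- present[!keep]

  prof <- data.frame(mirna_id = present[keep], stringsAsFactors = FALSE)
  prof$n_all_targets <- lengths(all_t[keep])
  prof$n_deg_targets <- lengths(deg_t[keep])
  prof$all_targets <- I(unname(all_t[keep]))
  prof$deg_targets <- I(unname(deg_t[keep]))
  prof$module_hits <- I(rep(list(list()), sum(keep)))
  prof$selected <- logical(sum(keep))
  rownames(prof) <- NULL
  structure(prof, dropped = dropped, unmapped = unmapped,
            class = c("mirna_profiles", "data.frame"))
}

#' Flag the lncRNA's direct gene targets as DEG / non-DEG
#'
#' Pure annotation, no filtering: each direct gene target of the lncRNA is
#' marked by membership in the DEG set.
#'
#' @param lnc_genes Character vector of direct lncRNA gene targets.
#' @param deg_genes Character vector of DEG identifiers.
#' @return Data frame with columns `gene_id` and `status`
#'   (`"DEG"`/`"non-DEG"`), sorted by `gene_id`.
#' @export
flag_gene_targets <- function(lnc_genes, deg_genes) {
  lnc_genes <- sort(unique(as.character(lnc_genes)))
  data.frame(gene_id = lnc_genes,
             status = ifelse(lnc_genes %in% deg_genes, "DEG", "non-DEG"),
             stringsAsFactors = FALSE)
}

#' Write profiles to TSV
#'
#' One row per retained miRNA: identifier, target counts, and the DEG targets
#' comma-joined.
#' @param profiles A `mirna_profiles` object.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  write_tsv(data.frame(
    mirna_id = profiles$mirna_id,
    n_all_targets = profiles$n_all_targets,
    n_deg_targets = profiles$n_deg_targets,
    deg_targets = vapply(profiles$deg_targets, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  ), path)
}
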
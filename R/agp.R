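#' AGP v2.1 component maps
#'
#' AGP records describe how an object (a pseudo-chromosome or scaffold) is
#' tiled from sequence components (`W` rows) and gaps (`N` rows). The tidy
#' representation is one tibble row per part with columns `object`,
#' `object_beg`, `object_end` (1-based inclusive, per the AGP standard),
#' `part_number`, `component_type`, and either `component_id`,
#' `component_beg`, `component_end`, `orientation` (W) or `gap_length`,
#' `gap_type`, `linkage` (N). The tiling invariant — parts cover the object
#' contiguously without overlap, spans consistent with coordinates — is
#' validated on read and on construction.
#'
#' @name agp
NULL

agp_cols <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "component_id", "component_beg",
              "component_end", "orientation", "gap_length", "gap_type",
              "linkage")

validate_agp <- function(agp) {
  miss <- setdiff(agp_cols, names(agp))
  if (length(miss) > 0L) stopf("AGP table missing columns: %s",
                               paste(miss, collapse = ", "))
  if (!all(agp$component_type %in% c("W", "N"))) {
    stopf("component_type must be W or N")
  }
  for (obj in unique(agp$object)) {
    part <- agp[agp$object == obj, ]
    part <- part[order(part$part_number), ]
    if (!identical(as.integer(part$part_number), seq_len(nrow(part)))) {
      stopf("object %s: part_number must increment by 1", obj)
    }
    expect_beg <- c(1L, part$object_end[-nrow(part)] + 1L)
    bad <- which(part$object_beg != expect_beg)
    if (length(bad) > 0L) {
      i <- bad[[1L]]
      stopf("object %s part %d: gap at object coordinates %d-%d",
            obj, part$part_number[i], expect_beg[i], part$object_beg[i] - 1L)
    }
    span <- part$object_end - part$object_beg + 1L
    comp_span <- ifelse(part$component_type == "W",
                        part$component_end - part$component_beg + 1L,
                        part$gap_length)
    if (any(span != comp_span)) {
      i <- which(span != comp_span)[[1L]]
      stopf("object %s part %d: object span %d != component span %d",
            obj, part$part_number[i], span[i], comp_span[i])
    }
  }
  invisible(agp)
}

#' Read an AGP v2.1 file
#'
#' Comment lines starting with `#` are skipped; the tiling invariant is
#' validated, with non-contiguous parts reported as a hard error naming the
#' object and part.
#'
#' @param path Path to an AGP file.
#' @return A validated AGP tibble (see [agp]).
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(object = character(), object_beg = integer(),
                  object_end = integer(), part_number = integer(),
                  component_type = character(), component_id = character(),
                  component_beg = integer(), component_end = integer(),
                  orientation = character(), gap_length = integer(),
                  gap_type = character(), linkage = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) stopf("AGP line %d has %d fields (expected >= 8)",
                          which(nf < 8L)[[1L]], nf[nf < 8L][[1L]])
  get <- function(i) purrr::map_chr(fields, ~ if (length(.x) >= i) .x[[i]] else NA_character_)
  type <- get(5L)
  agp <- tibble(
    object = get(1L),
    object_beg = as.integer(get(2L)),
    object_end = as.integer(get(3L)),
    part_number = as.integer(get(4L)),
    component_type = type,
    component_id = ifelse(type == "W", get(6L), NA_character_),
    component_beg = ifelse(type == "W", suppressWarnings(as.integer(get(7L))), NA_integer_),
    component_end = ifelse(type == "W", suppressWarnings(as.integer(get(8L))), NA_integer_),
    orientation = ifelse(type == "W", get(9L), NA_character_),
    gap_length = ifelse(type == "N", suppressWarnings(as.integer(get(6L))), NA_integer_),
    gap_type = ifelse(type == "N", get(7L), NA_character_),
    linkage = ifelse(type == "N", get(8L), NA_character_)
  )
  validate_agp(agp)
  agp
}

#' Write an AGP tibble to an AGP v2.1 file
#'
#' @param agp AGP tibble (see [agp]).
#' @param path Output path.
#' @param header Optional character vector of `#` comment lines to prepend.
#' @return `path`, invisibly. Data columns round-trip byte-identically
#'   through [read_agp()].
#' @export
write_agp <- function(agp, path, header = NULL) {
  validate_agp(agp)
  w <- agp$component_type == "W"
  col6 <- ifelse(w, agp$component_id, as.character(agp$gap_length))
  col7 <- ifelse(w, as.character(agp$component_beg), agp$gap_type)
  col8 <- ifelse(w, as.character(agp$component_end), agp$linkage)
  col9 <- ifelse(w, agp$orientation, "na")
  lines <- paste(agp$object, agp$object_beg, agp$object_end, agp$part_number,
                 agp$component_type, col6, col7, col8, col9, sep = "\t")
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Rebuild object sequences from an AGP table and component sequences
#'
#' The inverse of pseudo-chromosome emission: concatenates oriented component
#' slices and `N` gaps per object. Used to verify that AGP and FASTA outputs
#' describe the same bytes.
#'
#' @param agp AGP tibble.
#' @param components Assembly tibble holding every `component_id`.
#' @return Assembly tibble with one row per AGP object.
#' @export
agp_build <- function(agp, components) {
  validate_agp(agp)
  validate_assembly(components)
  comp_seq <- setNames(components$seq, components$id)
  objs <- unique(agp$object)
  seqs <- purrr::map_chr(objs, function(obj) {
    part <- agp[agp$object == obj, ]
    part <- part[order(part$part_number), ]
    pieces <- purrr::map_chr(seq_len(nrow(part)), function(i) {
      if (part$component_type[i] == "N") {
        strrep("N", part$gap_length[i])
      } else {
        cid <- part$component_id[i]
        if (!cid %in% names(comp_seq)) stopf("unknown component %s", cid)
        s <- substr(comp_seq[[cid]], part$component_beg[i], part$component_end[i])
        if (identical(part$orientation[i], "-")) revcomp(s) else s
      }
    })
    paste(pieces, collapse = "")
  })
  assembly(objs, seqs)
}
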
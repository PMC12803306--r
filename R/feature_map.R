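#' Construct a phenotype feature map
#'
#' A feature map is the disease-specific heart of a PheRS: an ordered list
#' of phenotype features, each a named group of version-qualified ICD codes
#' curated to represent one clinical manifestation (e.g. carpal tunnel
#' syndrome). A standard phecode-based map is just another instance of the
#' same structure.
#'
#' By default features must not share codes (`strict = TRUE`): the score
#' treats features as distinct manifestations, and a shared code would let
#' one diagnosis light up two features. Curated maps occasionally do
#' overlap on purpose, so `strict = FALSE` permits it and reports the
#' overlapping codes as a message instead.
#'
#' @param disease_name character scalar naming the target disease.
#' @param features long-format data.frame with columns
#'   `feature_id`, `feature_name`, `icd_version`, `code` (one row per code;
#'   codes are normalized on construction).
#' @param strict enforce cross-feature code disjointness (default `TRUE`).
#' @return object of class `feature_map`: list with `disease_name`,
#'   `features` (the normalized long table), `feature_ids` (ordered unique
#'   ids), `feature_names` (named by id).
#' @export
feature_map <- function(disease_name, features, strict = TRUE) {
  required <- c("feature_id", "feature_name", "icd_version", "code")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0L) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(features) == 0L) stop("feature map has no codes", call. = FALSE)
  ver <- suppressWarnings(as.integer(features$icd_version))
  if (any(is.na(ver)) || !all(ver %in% c(9L, 10L))) {
    stop("icd_version must be 9 or 10 for every code", call. = FALSE)
  }
  feats <- data.frame(
    feature_id = as.character(features$feature_id),
    feature_name = as.character(features$feature_name),
    icd_version = ver,
    code = normalize_icd(features$code),
    stringsAsFactors = FALSE
  )
  # one human label per feature id
  name_map <- unique(feats[, c("feature_id", "feature_name")])
  if (anyDuplicated(name_map$feature_id)) {
    dup <- unique(name_map$feature_id[duplicated(name_map$feature_id)])
    stop("feature_id with conflicting feature_name: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(name_map$feature_id, feats$feature_id[feats$code != ""])
  if (length(empty) > 0L) {
    stop("feature(s) with no codes: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  # drop exact duplicate (feature, code) rows, keep first occurrence order
  key <- paste(feats$feature_id, code_key(feats$icd_version, feats$code))
  feats <- feats[!duplicated(key), , drop = FALSE]
  rownames(feats) <- NULL
  ckey <- code_key(feats$icd_version, feats$code)
  shared <- unique(ckey[duplicated(ckey)])
  if (length(shared) > 0L) {
    if (strict) {
      stop("code(s) shared across features (strict mode): ",
           paste(utils::head(shared, 10L), collapse = ", "), call. = FALSE)
    }
    message("feature map has ", length(shared),
            " code(s) shared across features: ",
            paste(utils::head(shared, 10L), collapse = ", "))
  }
  ids <- unique(feats$feature_id)
  fnames <- name_map$feature_name[match(ids, name_map$feature_id)]
  names(fnames) <- ids
  structure(
    list(disease_name = as.character(disease_name)[1L],
         features = feats,
         feature_ids = ids,
         feature_names = fnames),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s: %d features, %d codes\n",
              x$disease_name, length(x$feature_ids), nrow(x$features)))
  invisible(x)
}

#' Number of features in a feature map
#' @param x a `feature_map`.
#' @param ... ignored.
#' @export
length.feature_map <- function(x) length(x$feature_ids)

#' Load a feature map from JSON or CSV
#'
#' JSON schema:
#' \preformatted{
#' {"disease_name": str,
#'  "features": [{"feature_id": str, "feature_name": str,
#'                "codes": [{"version": 9|10, "code": str}, ...]}, ...]}
#' }
#' CSV alternative: long format with header
#' `feature_id,feature_name,icd_version,code`. Both encodings produce
#' identical maps. The format is picked by file extension (`.json` vs
#' anything else).
#'
#' @param path path to the map file.
#' @param strict enforce cross-feature code disjointness (default `TRUE`).
#' @param disease_name disease label for CSV input (JSON carries its own).
#' @return a [feature_map].
#' @export
load_feature_map <- function(path, strict = TRUE, disease_name = "disease") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    feats <- spec$features
    if (is.null(feats) || length(feats) == 0L) {
      stop("feature map JSON has no features", call. = FALSE)
    }
    rows <- lapply(seq_len(nrow(feats)), function(i) {
      codes <- feats$codes[[i]]
      if (is.null(codes) || nrow(codes) == 0L) {
        stop("feature '", feats$feature_id[i], "' has no codes",
             call. = FALSE)
      }
      data.frame(feature_id = feats$feature_id[i],
                 feature_name = feats$feature_name[i],
                 icd_version = codes$version,
                 code = codes$code,
                 stringsAsFactors = FALSE)
    })
    long <- do.call(rbind, rows)
    dn <- spec$disease_name %||% disease_name
  } else {
    long <- utils::read.csv(path, colClasses = "character",
                            check.names = FALSE)
    check_columns(long, c("feature_id", "feature_name", "icd_version",
                          "code"), "feature map", path)
    dn <- disease_name
  }
  if (anyDuplicated(unique(long[, c("feature_id", "feature_name")])$feature_id)) {
    stop("duplicate feature_id with conflicting names in ", path,
         call. = FALSE)
  }
  map <- feature_map(dn, long, strict = strict)
  message(sprintf("loaded feature map '%s': %d features, %d codes",
                  map$disease_name, length(map$feature_ids),
                  nrow(map$features)))
  map
}

#' Write a feature map as JSON
#' @param map a [feature_map].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_feature_map <- function(map, path) {
  feats <- lapply(map$feature_ids, function(fid) {
    sub <- map$features[map$features$feature_id == fid, , drop = FALSE]
    list(feature_id = fid,
         feature_name = unname(map$feature_names[[fid]]),
         codes = data.frame(version = sub$icd_version, code = sub$code))
  })
  jsonlite::write_json(
    list(disease_name = map$disease_name, features = feats),
    path, auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Construct or load a code catalog
#'
#' The catalog enumerates every (version, code) pair that exists in the
#' user's coding-system extract; it stands in for the licensed ICD
#' tabulations when expanding seed codes to their hierarchy descendants
#' (which, on normalized codes, is a string-prefix relation).
#'
#' @param catalog data.frame with columns `icd_version`, `code`.
#' @return normalized, deduplicated data.frame of class `code_catalog`.
#' @export
code_catalog <- function(catalog) {
  check_columns(catalog, c("icd_version", "code"), "catalog", "<in-memory>")
  if (nrow(catalog) == 0L) stop("code catalog is empty", call. = FALSE)
  out <- data.frame(
    icd_version = as.integer(catalog$icd_version),
    code = normalize_icd(catalog$code),
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(code_key(out$icd_version, out$code)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("code_catalog", "data.frame")
  out
}

#' @rdname code_catalog
#' @param path CSV with header `icd_version,code`.
#' @export
load_code_catalog <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  code_catalog(df)
}

#' Expand seed codes to their hierarchy descendants
#'
#' A catalog entry is a descendant of a seed when both share the ICD
#' version and the entry's normalized code string starts with the seed's
#' (e.g. seed `I50` covers `I50`, `I509`, `I5021`, ...). A seed present in
#' the catalog is itself included; a seed with no catalog match at all
#' contributes nothing and triggers a warning.
#'
#' @param seeds data.frame with columns `icd_version`, `code` (normalized
#'   on entry).
#' @param catalog a [code_catalog] (or coercible data.frame).
#' @return data.frame (`icd_version`, `code`) of all matching catalog
#'   entries, deduplicated, in catalog order.
#' @export
expand_hierarchy <- function(seeds, catalog) {
  catalog <- code_catalog(catalog)
  if (nrow(seeds) == 0L) {
    return(catalog[0L, c("icd_version", "code"), drop = FALSE])
  }
  seeds <- data.frame(icd_version = as.integer(seeds$icd_version),
                      code = normalize_icd(seeds$code),
                      stringsAsFactors = FALSE)
  hit <- rep(FALSE, nrow(catalog))
  unmatched <- character(0)
  for (i in seq_len(nrow(seeds))) {
    m <- catalog$icd_version == seeds$icd_version[i] &
      startsWith(catalog$code, seeds$code[i])
    if (!any(m)) {
      unmatched <- c(unmatched,
                     code_key(seeds$icd_version[i], seeds$code[i]))
    }
    hit <- hit | m
  }
  if (length(unmatched) > 0L) {
    warning("seed code(s) with no catalog match: ",
            paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  out <- catalog[hit, c("icd_version", "code"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Remove target-disease diagnosis codes from a feature map
#'
#' When a PheRS is meant to find undiagnosed patients, codes that record an
#' actual diagnosis of the target disease (e.g. `Q87.4` and its descendants
#' for Marfan syndrome) leak the label into the score and must be excluded.
#' The seeds are expanded against the catalog ([expand_hierarchy()]) and
#' every resulting code is removed from every feature. Features left with
#' no codes are dropped with a warning. The input map is not modified.
#'
#' @param map a [feature_map].
#' @param disease_seed_codes data.frame (`icd_version`, `code`) of seed
#'   codes identifying the disease diagnosis itself.
#' @param catalog a [code_catalog] used for expansion.
#' @return a new [feature_map] without the excluded codes.
#' @export
exclude_disease_codes <- function(map, disease_seed_codes, catalog) {
  excl <- expand_hierarchy(disease_seed_codes, catalog)
  excl_keys <- code_key(excl$icd_version, excl$code)
  feats <- map$features
  keep <- !code_key(feats$icd_version, feats$code) %in% excl_keys
  kept <- feats[keep, , drop = FALSE]
  dropped <- setdiff(map$feature_ids, unique(kept$feature_id))
  if (length(dropped) > 0L) {
    warning("feature(s) dropped (all codes excluded): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nrow(kept) == 0L) {
    stop("exclusion removed every code in the feature map", call. = FALSE)
  }
  feature_map(map$disease_name, kept, strict = FALSE)
}

#' Per-patient binary phenotype presence
#'
#' A feature is present for a patient iff at least one diagnosis event
#' carries one of the feature's (version, code) pairs — anywhere in the
#' record, any date. Duplicate events collapse; patients with no mapped
#' diagnoses (including patients absent from the diagnosis table entirely)
#' get an all-zero row.
#'
#' @param diagnoses data.frame as from [read_diagnoses()].
#' @param map a [feature_map].
#' @param patients character vector: the ordered patient universe to score.
#' @return integer 0/1 matrix, `length(patients)` rows x one column per
#'   feature (map order), dimnames = patients x feature ids.
#' @export
presence_matrix <- function(diagnoses, map, patients) {
  patients <- as.character(patients)
  if (anyDuplicated(patients)) {
    stop("duplicate patient ids in 'patients'", call. = FALSE)
  }
  mat <- matrix(0L, nrow = length(patients),
                ncol = length(map$feature_ids),
                dimnames = list(patients, map$feature_ids))
  if (nrow(diagnoses) == 0L || length(patients) == 0L) return(mat)
  ev_key <- code_key(diagnoses$icd_version, diagnoses$icd_code)
  code2feat <- data.frame(
    key = code_key(map$features$icd_version, map$features$code),
    feature_id = map$features$feature_id,
    stringsAsFactors = FALSE
  )
  ev <- data.frame(patient_id = diagnoses$patient_id, key = ev_key,
                   stringsAsFactors = FALSE)
  ev <- ev[!duplicated(paste(ev$patient_id, ev$key)), , drop = FALSE]
  hits <- merge(ev, code2feat, by = "key")
  if (nrow(hits) == 0L) return(mat)
  ri <- match(hits$patient_id, patients)
  ci <- match(hits$feature_id, map$feature_ids)
  ok <- !is.na(ri)
  mat[cbind(ri[ok], ci[ok])] <- 1L
  mat
}
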
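# Plain-text pedigree interchange: a PED-like TSV with a header line and
# `#`-prefixed metadata. Parent id 0 means unknown (founder); an empty death
# year means alive at the final year. Write -> read -> write is
# byte-identical, so files are auditable and diffable.

#' Write a pedigree to a PED-like TSV file
#'
#' Columns: `id`, `sex` (`F`/`M`), `birth_year`, `death_year` (empty = alive
#' at the final year), `mother_id`, `father_id` (0 = unknown parent).
#' Metadata (`final_year`, `seed`, and the full species parameterisation) is
#' stored in `#`-prefixed header lines so the file round-trips into an
#' identical object.
#'
#' @param pedigree A [kin_pedigree][ped_params].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  p <- ped_params(pedigree)
  meta <- c(
    sprintf("# final_year=%d", ped_final_year(pedigree)),
    sprintf("# seed=%d", ped_seed(pedigree)),
    sprintf("# species.%s=%s", names(unclass(p)),
            vapply(unclass(p), function(v) format(v, digits = 15),
                   character(1)))
  )
  tbl <- pedigree %>%
    as_tibble() %>%
    mutate(
      mother_id = ifelse(is.na(.data$mother_id), 0L, .data$mother_id),
      father_id = ifelse(is.na(.data$father_id), 0L, .data$father_id)
    )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(names(tbl), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(tbl, function(col) {
    out <- as.character(col)
    out[is.na(col)] <- ""
    out
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a pedigree from a PED-like TSV file
#'
#' Inverse of [write_pedigree()]. Files written by other tools may omit the
#' metadata lines, in which case `params` must be supplied and the final year
#' defaults to the latest birth or death year observed.
#'
#' @param path Input path.
#' @param params Optional [species_params()] overriding (or supplying) the
#'   file's species metadata.
#' @return A [kin_pedigree][ped_params].
#' @export
read_pedigree <- function(path, params = NULL) {
  if (!file.exists(path)) {
    stop("pedigree file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  meta_mask <- startsWith(lines, "#")
  meta <- lines[meta_mask]
  tbl <- readr::read_tsv(
    I(paste(lines[!meta_mask], collapse = "\n")),
    col_types = readr::cols(
      id = readr::col_integer(), sex = readr::col_character(),
      birth_year = readr::col_integer(), death_year = readr::col_integer(),
      mother_id = readr::col_integer(), father_id = readr::col_integer()
    ),
    progress = FALSE
  ) %>%
    mutate(
      mother_id = ifelse(.data$mother_id == 0L, NA_integer_, .data$mother_id),
      father_id = ifelse(.data$father_id == 0L, NA_integer_, .data$father_id)
    )
  kv <- sub("^#\\s*", "", meta)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta_of <- setNames(vals, keys)
  final_year <- if ("final_year" %in% keys) {
    as.integer(meta_of[["final_year"]])
  } else {
    max(c(tbl$birth_year, tbl$death_year), na.rm = TRUE)
  }
  seed <- if ("seed" %in% keys) as.integer(meta_of[["seed"]]) else NA_integer_
  if (is.null(params)) {
    sp <- keys[startsWith(keys, "species.")]
    if (!length(sp)) {
      stop("file has no species metadata; supply `params`", call. = FALSE)
    }
    raw <- as.list(meta_of[sp])
    names(raw) <- sub("^species\\.", "", sp)
    num <- setdiff(names(raw), "name")
    raw[num] <- lapply(raw[num], as.numeric)
    params <- validate_species_params(raw)
  }
  new_kin_pedigree(tbl, params = params, final_year = final_year, seed = seed)
}
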
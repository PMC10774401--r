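#' Read a NanoString RCC lane file
#'
#' Parses the instrument's per-lane text format: tag-delimited
#' `<Section>` ... `</Section>` blocks with CSV bodies. The `Code_Summary`
#' section (columns `CodeClass,Name,Accession,Count`) carries the probe
#' counts; `Header`, `Sample_Attributes` and `Lane_Attributes` are returned as
#' metadata. Unknown sections are preserved in the metadata but otherwise
#' ignored.
#'
#' @param path path to an `.RCC` file (UTF-8 text).
#' @return a list with elements `counts` (named integer vector over probe
#'   names), `codeClass` (named character vector, same names) and `metadata`
#'   (list of key-value sections).
#' @examples
#' f <- tempfile(fileext = ".RCC")
#' writeRcc(f, counts = c(Aif1 = 120L, Ccl5 = 8L),
#'          codeClass = c("Endogenous", "Endogenous"))
#' readRcc(f)$counts
#' @export
readRcc <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sections <- splitRccSections(lines)
  if (!"Code_Summary" %in% names(sections))
    stop("RCC format error: missing Code_Summary section in ", path,
         call. = FALSE)
  body <- sections[["Code_Summary"]]
  tab <- utils::read.csv(text = body, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% colnames(tab)))
    stop("RCC format error: Code_Summary must have CodeClass, Name, Count columns",
         call. = FALSE)
  cnt <- suppressWarnings(as.numeric(tab$Count))
  bad <- is.na(cnt) | cnt != floor(cnt) | cnt < 0
  if (any(bad))
    stop(sprintf("RCC format error: non-integer count for probe(s): %s",
                 paste(utils::head(tab$Name[bad], 5), collapse = ", ")),
         call. = FALSE)
  meta <- lapply(sections[setdiff(names(sections), "Code_Summary")],
                 parseKvSection)
  list(counts = stats::setNames(as.integer(cnt), tab$Name),
       codeClass = stats::setNames(tab$CodeClass, tab$Name),
       metadata = meta)
}

splitRccSections <- function(lines) {
  open <- grep("^<[^/][^>]*>\\s*$", lines)
  out <- list()
  for (i in open) {
    nm <- sub("^<([^>]*)>\\s*$", "\\1", lines[i])
    close <- grep(sprintf("^</%s>\\s*$", nm), lines)
    close <- close[close > i][1]
    if (is.na(close))
      stop(sprintf("RCC format error: unterminated section <%s>", nm),
           call. = FALSE)
    out[[nm]] <- paste(lines[(i + 1):(close - 1)], collapse = "\n")
  }
  out
}

parseKvSection <- function(body) {
  rows <- strsplit(strsplit(body, "\n")[[1]], ",")
  vals <- lapply(rows, function(r) paste(r[-1], collapse = ","))
  stats::setNames(vals, vapply(rows, `[`, "", 1))
}

#' Write a single-lane RCC file
#'
#' Emits the minimal section structure [readRcc()] consumes; used to build
#' fixtures and to export simulated lanes in the instrument format.
#'
#' @param path output path.
#' @param counts named integer vector (probe name -> count).
#' @param codeClass character vector of probe classes, recycled if length 1.
#' @param laneId lane identifier written to `Lane_Attributes`.
#' @return `path`, invisibly.
#' @export
writeRcc <- function(path, counts, codeClass = "Endogenous",
                     laneId = "lane_01") {
  stopifnot(!is.null(names(counts)), all(counts == floor(counts)),
            all(counts >= 0))
  codeClass <- rep_len(codeClass, length(counts))
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>", paste0("ID,", laneId), "</Sample_Attributes>",
    "<Lane_Attributes>", paste0("ID,", laneId), "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,NA,%d", codeClass, names(counts), as.integer(counts)),
    "</Code_Summary>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
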
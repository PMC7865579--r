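# Reading and writing the simplified RCC lane dialect:
#   <Header> key,value </Header>
#   <Lane_Attributes> key,value </Lane_Attributes>
#   <Code_Summary> CodeClass,Name,Accession,Count (CSV rows) </Code_Summary>

.NUMERIC_ATTRS <- c("FovCount", "FovCounted", "BindingDensity")

#' Write an RCC lane file
#'
#' Serializes one [RccLane-class] to the sectioned RCC text dialect. The
#' file round-trips losslessly through [readRcc()]: counts are written as
#' integers (zero counts as `0`, never blank) and numeric attributes at
#' full precision.
#'
#' @param lane An [RccLane-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRcc <- function(lane, path) {
  validObject(lane)
  fmt <- function(v) {
    if (is.numeric(v)) format(v, digits = 15, scientific = FALSE) else
      as.character(v)
  }
  at <- lane@attributes
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,gliomaTP", "</Header>",
    "<Lane_Attributes>",
    paste0(names(at), ",", vapply(at, fmt, character(1))),
    "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,%s,%d", lane@counts$CodeClass, lane@counts$Name,
            lane@counts$Accession, as.integer(lane@counts$Count)),
    "</Code_Summary>")
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort of lanes, one RCC file per sample
#'
#' @param lanes list of [RccLane-class].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, named by sample id.
#' @export
writeRccSet <- function(lanes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(lanes, function(l) {
    p <- file.path(dir, paste0(laneSampleId(l), ".rcc"))
    writeRcc(l, p)
    p
  }, character(1))
  setNames(paths, vapply(lanes, laneSampleId, character(1)))
}

# split the file into named sections, insisting on well-formed markers
.rcc_sections <- function(lines, path) {
  open_idx <- grep("^<[A-Za-z_]+>$", lines)
  close_idx <- grep("^</[A-Za-z_]+>$", lines)
  if (length(open_idx) != length(close_idx))
    stop("malformed RCC '", path, "': unbalanced section markers")
  sections <- list()
  for (i in seq_along(open_idx)) {
    name <- sub("^<([A-Za-z_]+)>$", "\\1", lines[open_idx[i]])
    close_name <- sub("^</([A-Za-z_]+)>$", "\\1", lines[close_idx[i]])
    if (!identical(name, close_name) || close_idx[i] <= open_idx[i])
      stop("malformed RCC '", path, "': section <", name,
           "> not closed properly")
    body <- lines[seq(open_idx[i] + 1L, close_idx[i] - 1L)]
    sections[[name]] <- list(body = body, start = open_idx[i])
  }
  sections
}

#' Read an RCC lane file
#'
#' Parses one lane from the sectioned RCC text dialect. Counts must be
#' plain non-negative integers; any malformed line is reported by number.
#' If a `panel` is supplied, the lane is checked to contain every panel
#' probe and any probe not in the panel is reported with a warning (never
#' silently dropped).
#'
#' @param path RCC file path.
#' @param panel optional [PanelDefinition-class] to validate against.
#' @return An [RccLane-class].
#' @export
readRcc <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  sections <- .rcc_sections(lines, path)
  if (is.null(sections$Lane_Attributes))
    stop("malformed RCC '", path, "': missing Lane_Attributes section")
  if (is.null(sections$Code_Summary))
    stop("malformed RCC '", path, "': missing Code_Summary section")

  attrs <- list()
  for (ln in sections$Lane_Attributes$body) {
    kv <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- kv[1]
    val <- paste(kv[-1], collapse = ",")
    if (key %in% .NUMERIC_ATTRS) {
      val <- if (grepl("^-?[0-9]+$", val)) as.integer(val) else
        as.numeric(val)
    }
    attrs[[key]] <- val
  }

  body <- sections$Code_Summary$body
  start <- sections$Code_Summary$start
  if (!length(body) || !grepl("^CodeClass,Name,Accession,Count$", body[1]))
    stop("malformed RCC '", path, "': Code_Summary header row missing")
  rows <- body[-1]
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad_shape <- which(lengths(parts) != 4L)
  if (length(bad_shape))
    stop("parse error in '", path, "' line ",
         start + 1L + bad_shape[1], ": expected 4 comma-separated fields")
  m <- do.call(rbind, parts)
  count_str <- m[, 4]
  bad <- which(!grepl("^[0-9]+$", count_str))
  if (length(bad))
    stop("parse error in '", path, "' line ", start + 1L + bad[1],
         ": count '", count_str[bad[1]],
         "' is not a non-negative integer")
  counts <- data.frame(CodeClass = m[, 1], Name = m[, 2], Accession = m[, 3],
                       Count = as.integer(count_str),
                       stringsAsFactors = FALSE)

  sample_id <- attrs$ID %||% sub("\\.rcc$", "", basename(path))
  lane <- RccLane(sample_id, attrs, counts)

  if (!is.null(panel)) {
    missing <- setdiff(panelProbes(panel), counts$Name)
    if (length(missing))
      stop("lane '", sample_id, "' is missing panel probes: ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ...")
    unknown <- setdiff(counts$Name, panelProbes(panel))
    if (length(unknown))
      warning("lane '", sample_id, "' contains probes not in the panel: ",
              paste(head(unknown, 5), collapse = ", "),
              if (length(unknown) > 5) ", ...")
  }
  lane
}

#' Read a directory of RCC files
#'
#' @param dir directory containing `*.rcc` files.
#' @param panel optional [PanelDefinition-class].
#' @return named list of [RccLane-class], keyed by sample id.
#' @export
readRccSet <- function(dir, panel = NULL) {
  files <- sort(list.files(dir, pattern = "\\.rcc$", full.names = TRUE))
  if (!length(files)) stop("no .rcc files under ", dir)
  lanes <- lapply(files, readRcc, panel = panel)
  setNames(lanes, vapply(lanes, laneSampleId, character(1)))
}

#' Write a panel definition as CSV
#' @param panel A [PanelDefinition-class].
#' @param path output file.
#' @export
writePanel <- function(panel, path) {
  write.csv(panel@probes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a panel definition from CSV (`name,code_class,pattern_group`)
#' @param path CSV file.
#' @return A [PanelDefinition-class].
#' @export
readPanel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  PanelDefinition(df$name, df$code_class, df$pattern_group)
}
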
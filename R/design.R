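#' Barcode design: layout of random and fixed bases within a barcode region
#'
#' A barcode design declares, for one template family, the length of the
#' barcode region at the 5' end of the read, which barcode positions carry
#' random bases, which positions carry designed fixed (anchor) bases and what
#' those bases are, where the target sequence sits in the read, and the
#' accepted read-length window.  All coordinates are 1-based and inclusive,
#' counted from the 5' end of the read as sequenced.
#'
#' Random and fixed positions must be disjoint and must together cover every
#' position `1..barcode_length` exactly once.
#'
#' @param name Label for the design (e.g. `"short_template"`).
#' @param barcode_length Integer, total length of the barcode region in bases.
#' @param random_positions Integer vector of 1-based barcode positions that
#'   carry random bases.
#' @param fixed_positions Integer vector of 1-based barcode positions that
#'   carry fixed bases.
#' @param fixed_bases Character vector of expected bases (one of A/C/G/T),
#'   parallel to `fixed_positions`.
#' @param target_region Length-2 integer vector `(start, end)`: 1-based
#'   inclusive coordinates of the target sequence within the read.
#' @param length_window Length-2 numeric vector `(min_len, max_len)` of
#'   accepted read lengths; use `Inf` for an unbounded maximum.
#' @return An object of class `barcode_design`.
#' @examples
#' d <- default_design("short_template")
#' d$barcode_length                       # 30
#' length(d$random_positions)             # 24
#' @export
barcode_design <- function(name, barcode_length, random_positions,
                           fixed_positions, fixed_bases,
                           target_region, length_window) {
  barcode_length <- as.integer(barcode_length)
  random_positions <- as.integer(random_positions)
  fixed_positions <- as.integer(fixed_positions)
  fixed_bases <- toupper(as.character(fixed_bases))
  if (length(fixed_positions) != length(fixed_bases))
    stop("fixed_positions and fixed_bases must have equal length")
  if (!all(fixed_bases %in% c("A", "C", "G", "T")))
    stop("fixed_bases must be A, C, G or T")
  all_pos <- c(random_positions, fixed_positions)
  bad <- all_pos[all_pos < 1L | all_pos > barcode_length]
  if (length(bad))
    stop("barcode position(s) out of range 1..", barcode_length, ": ",
         paste(bad, collapse = ", "))
  dup <- all_pos[duplicated(all_pos)]
  if (length(dup))
    stop("barcode position(s) listed more than once: ",
         paste(unique(dup), collapse = ", "))
  if (length(all_pos) != barcode_length)
    stop("random and fixed positions must cover all ", barcode_length,
         " barcode positions (got ", length(all_pos), ")")
  target_region <- as.integer(target_region)
  if (length(target_region) != 2L || target_region[1] > target_region[2])
    stop("target_region must be (start, end) with start <= end")
  length_window <- as.numeric(length_window)
  if (length(length_window) != 2L || length_window[1] > length_window[2])
    stop("length_window must be (min_len, max_len) with min <= max")
  o <- order(fixed_positions)
  structure(list(
    name = as.character(name),
    barcode_length = barcode_length,
    random_positions = sort(random_positions),
    fixed_positions = fixed_positions[o],
    fixed_bases = fixed_bases[o],
    target_region = target_region,
    length_window = length_window
  ), class = "barcode_design")
}

#' @export
print.barcode_design <- function(x, ...) {
  cat("Barcode design '", x$name, "': ", x$barcode_length, " bases (",
      length(x$random_positions), " random + ",
      length(x$fixed_positions), " fixed)\n", sep = "")
  cat("  fixed bases: ",
      paste0(x$fixed_bases, "@", x$fixed_positions, collapse = " "), "\n",
      sep = "")
  cat("  target region: ", x$target_region[1], "-", x$target_region[2],
      "; read length window: [", x$length_window[1], ", ",
      x$length_window[2], "]\n", sep = "")
  invisible(x)
}

#' Bundled default barcode designs
#'
#' Two designs are bundled:
#' \describe{
#'   \item{`short_template`}{30-base barcode = 24 random + 6 fixed bases,
#'     8-base target at read positions 31-38, read-length window 34-39.
#'     The four fixed bases furthest from the sequencing primer sit at
#'     barcode positions 16, 21, 24 and 28 and form the default
#'     fixed-base filter set.}
#'   \item{`long_template`}{50-base barcode = 38 random + 12 fixed bases,
#'     50-base target at read positions 51-100, read-length window >= 90.}
#' }
#'
#' The positions and identities of the fixed bases are a synthetic layout
#' consistent with the published design geometry (the original oligo table
#' is vendor-supplied); both are plain data and can be replaced by loading a
#' design config with [load_design()].
#'
#' @param name `"short_template"` or `"long_template"`.
#' @return A [barcode_design()] object.
#' @export
default_design <- function(name = c("short_template", "long_template")) {
  name <- match.arg(name)
  if (name == "short_template") {
    fixed_pos <- c(5L, 10L, 16L, 21L, 24L, 28L)
    barcode_design(
      name = "short_template",
      barcode_length = 30L,
      random_positions = setdiff(1:30, fixed_pos),
      fixed_positions = fixed_pos,
      fixed_bases = c("C", "A", "G", "T", "A", "C"),
      target_region = c(31L, 38L),
      length_window = c(34, 39)
    )
  } else {
    fixed_pos <- c(4L, 8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L, 40L, 45L, 50L)
    barcode_design(
      name = "long_template",
      barcode_length = 50L,
      random_positions = setdiff(1:50, fixed_pos),
      fixed_positions = fixed_pos,
      fixed_bases = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C",
                      "G", "T"),
      target_region = c(51L, 100L),
      length_window = c(90, Inf)
    )
  }
}

#' Load / serialize a barcode design config (YAML or JSON)
#'
#' The config is a mapping with keys `name`, `barcode_length`,
#' `random_positions`, `fixed_positions` (mapping or list of
#' `position: base` pairs), `target_region` (`[start, end]`) and
#' `length_window` (`[min, max]`, `.inf`/`null` max allowed).  All positions
#' are 1-based on the read from the 5' end.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` design file.
#' @param text Config given directly as a string (overrides `path`).
#' @param format `"yaml"` or `"json"`; guessed from the file extension when
#'   loading from `path`.
#' @return A [barcode_design()] object.
#' @seealso [write_design()] for the inverse.
#' @export
load_design <- function(path = NULL, text = NULL,
                        format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (is.null(text)) {
    if (is.null(path)) stop("give either path or text")
    if (format == "auto")
      format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
                else "yaml"
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  } else if (format == "auto") {
    format <- if (grepl("^\\s*\\{", text)) "json" else "yaml"
  }
  x <- if (format == "json") jsonlite::fromJSON(text, simplifyVector = TRUE)
       else yaml::yaml.load(text)
  need <- c("name", "barcode_length", "random_positions", "fixed_positions",
            "target_region", "length_window")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("design config missing field(s): ", paste(miss, collapse = ", "))
  fp <- x$fixed_positions
  if (is.list(fp) || !is.null(names(fp))) {
    fp <- unlist(fp)
    positions <- as.integer(names(fp))
    bases <- as.character(fp)
  } else stop("fixed_positions must map position -> expected base")
  win <- unlist(x$length_window)
  win <- ifelse(is.na(win) | is.null(win), Inf, as.numeric(win))
  if (length(win) == 1L) win <- c(win, Inf)
  barcode_design(
    name = x$name,
    barcode_length = x$barcode_length,
    random_positions = unlist(x$random_positions),
    fixed_positions = positions,
    fixed_bases = bases,
    target_region = unlist(x$target_region),
    length_window = win
  )
}

#' @rdname load_design
#' @param design A [barcode_design()] object to serialize.
#' @export
write_design <- function(design, path = NULL, format = c("yaml", "json")) {
  stopifnot(inherits(design, "barcode_design"))
  format <- match.arg(format)
  fixed <- as.list(design$fixed_bases)
  names(fixed) <- as.character(design$fixed_positions)
  obj <- list(
    name = design$name,
    barcode_length = design$barcode_length,
    random_positions = design$random_positions,
    fixed_positions = fixed,
    target_region = design$target_region,
    length_window = ifelse(is.infinite(design$length_window), NA,
                           design$length_window)
  )
  text <- if (format == "json")
    jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = TRUE, na = "null")
  else yaml::as.yaml(obj)
  if (!is.null(path)) writeLines(as.character(text), path)
  invisible(as.character(text))
}

#' Number of distinct barcode sequences a design can produce
#'
#' The combinatorial capacity of the random-base region: `4^k` for `k`
#' random bases (e.g. 24 random bases give 4^24, about 2.8e14 sequences).
#' This bounds the number of molecules that can in principle be labeled
#' uniquely.
#'
#' @param design A [barcode_design()], or an integer number of random bases.
#' @return A double (the capacity exceeds integer range for typical designs).
#' @export
barcode_space_size <- function(design) {
  k <- if (inherits(design, "barcode_design"))
    length(design$random_positions) else as.numeric(design)
  4^k
}

#' Select fixed-base positions for filtering
#'
#' The fixed-base filter need not use every designed fixed base.  Selection
#' is either explicit (a vector of barcode positions, all of which must be
#' fixed positions of the design) or `"furthest:k"`: the k fixed bases
#' furthest from the sequencing primer site (the primer is upstream of
#' barcode position 1, so "furthest" means the largest positions).
#'
#' @param design A [barcode_design()].
#' @param selection Integer vector of barcode positions, or a string
#'   `"furthest:k"`.  `NULL` selects every fixed position.
#' @return Integer vector of selected fixed positions, in increasing order.
#' @examples
#' select_fixed_positions(default_design("short_template"), "furthest:4")
#' # 16 21 24 28
#' @export
select_fixed_positions <- function(design, selection = NULL) {
  stopifnot(inherits(design, "barcode_design"))
  fp <- design$fixed_positions
  if (is.null(selection)) return(fp)
  if (is.character(selection)) {
    if (!grepl("^furthest:[0-9]+$", selection))
      stop("selection string must look like \"furthest:k\"")
    k <- as.integer(sub("^furthest:", "", selection))
    if (k < 1L || k > length(fp))
      stop("cannot select ", k, " of ", length(fp), " fixed bases")
    return(sort(utils::tail(sort(fp), k)))
  }
  selection <- as.integer(selection)
  bad <- setdiff(selection, fp)
  if (length(bad))
    stop("selected position(s) not fixed positions of the design: ",
         paste(bad, collapse = ", "))
  sort(selection)
}
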
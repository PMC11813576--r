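#' Load an experiment configuration
#'
#' Reads a YAML configuration with a `geometry` block (exactly one of
#' `plane_pores`, `mesh_file`, or `builder`), a `run` block (`M`, `seed`,
#' optional `D`, `reinsertion_ratio`, `release`), and optional `output` /
#' `theory` blocks.  Defaults are filled (`D = 1`, `reinsertion_ratio = 3`);
#' the release surface must be given explicitly.
#'
#' @param path YAML file.
#' @return validated `experiment_config` list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known_top <- c("geometry", "run", "output", "theory")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$geometry)) stop("config must contain a geometry block")
  sources <- intersect(names(cfg$geometry), c("plane_pores", "mesh_file", "builder"))
  if (length(sources) != 1L) {
    stop("geometry block must contain exactly one of plane_pores, mesh_file, builder")
  }
  if (is.null(cfg$run)) stop("config must contain a run block")
  run_known <- c("M", "seed", "D", "reinsertion_ratio", "release", "safety_cap")
  extra <- setdiff(names(cfg$run), run_known)
  if (length(extra)) stop("unknown run key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$run$M) || cfg$run$M <= 0) stop("run$M must be a positive count")
  if (is.null(cfg$run$D)) cfg$run$D <- 1
  if (cfg$run$D <= 0) stop("run$D must be positive")
  if (is.null(cfg$run$reinsertion_ratio)) cfg$run$reinsertion_ratio <- 3
  if (is.null(cfg$run$release)) {
    stop("run$release must be given explicitly (surface + radius, or point)")
  }
  structure(cfg, class = "experiment_config")
}

#' Write a configuration back to YAML
#'
#' @param cfg an `experiment_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  # small deterministic FNV-1a hash; provenance marker, not cryptographic
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Write capture records to a delimited text file
#'
#' Tab-separated table (one header line) preceded by `#`-comment metadata
#' lines recording the format version, seed and config hash.  Times are
#' written with 17 significant digits so the round-trip is lossless.
#'
#' @param records a `capture_records` data frame.
#' @param path output file.
#' @param seed,config_hash optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# kmcapture records v1",
               paste0("# seed: ", seed),
               paste0("# config_hash: ", config_hash)), con)
  df <- records
  for (col in c("time", "x", "y", "z")) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read capture records written by [write_records()]
#'
#' @param path file path.
#' @return a `capture_records` data frame; header metadata is attached as
#'   attributes `seed` and `config_hash`.  A version mismatch warns; a
#'   malformed row errors with its line number.
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  if (!length(meta) || !grepl("kmcapture records", meta[1])) {
    warning("missing or unrecognized records header")
  } else if (!grepl("v1$", meta[1])) {
    warning("records file version differs from v1; attempting to read anyway")
  }
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]]
  rows <- body[-1]
  if (length(rows)) {
    nf <- lengths(strsplit(rows, "\t"))
    # trailing empty fields are dropped by strsplit; allow short rows only
    # when the missing fields are the trailing optional ones
    bad <- which(nf > length(header))
    if (length(bad)) {
      stop("malformed record at line ", length(meta) + 1 + bad[1])
    }
  }
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          na.strings = "", stringsAsFactors = FALSE)
  df$outcome <- factor(df$outcome, levels = c("captured", "escaped", "lost"))
  class(df) <- c("capture_records", "data.frame")
  for (m in meta[-1]) {
    kv <- sub("^# *", "", m)
    key <- sub(":.*$", "", kv)
    attr(df, key) <- trimws(sub("^[^:]*: *", "", kv))
  }
  df
}

#' Write a polyhedral mesh to OFF or PLY (ASCII)
#'
#' The per-face absorber attribute (0 = reflecting, k >= 1 = absorber id) is
#' stored as an extra trailing integer on each face row (OFF) or as an
#' `absorber` face property (PLY).
#'
#' @param poly a [convex_polyhedron()].
#' @param path output path; format chosen by extension (`.off` / `.ply`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(poly, path) {
  fmt <- tolower(tools::file_ext(path))
  v <- poly$vertices
  f <- poly$faces
  vtxt <- apply(v, 1, function(r) paste(formatC(r, digits = 17, format = "g"),
                                        collapse = " "))
  if (fmt == "off") {
    ftxt <- vapply(seq_along(f), function(i) {
      paste(c(length(f[[i]]), f[[i]] - 1L, poly$absorber[i]), collapse = " ")
    }, character(1))
    writeLines(c("OFF", paste(nrow(v), length(f), 0), vtxt, ftxt), path)
  } else if (fmt == "ply") {
    ftxt <- vapply(seq_along(f), function(i) {
      paste(c(length(f[[i]]), f[[i]] - 1L, poly$absorber[i]), collapse = " ")
    }, character(1))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property double x", "property double y", "property double z",
                 paste("element face", length(f)),
                 "property list uchar int vertex_indices",
                 "property int absorber",
                 "end_header", vtxt, ftxt), path)
  } else {
    stop("unsupported mesh format: ", fmt)
  }
  invisible(path)
}

#' Read a polyhedral mesh from OFF or PLY (ASCII)
#'
#' Faces missing the absorber attribute are read as reflecting, with a
#' warning.  The mesh is validated on read (convexity, watertightness); a
#' non-convex input names the violating vertex/face pair.
#'
#' @param path input path (`.off` / `.ply`).
#' @return a [convex_polyhedron()].
#' @export
read_mesh <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (fmt == "off") {
    if (lines[1] != "OFF") stop("not an OFF file")
    counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    v <- do.call(rbind, lapply(lines[2 + seq_len(nv)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]][1:3])
    }))
    frows <- lapply(lines[2 + nv + seq_len(nf)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]])
    })
  } else if (fmt == "ply") {
    if (lines[1] != "ply") stop("not a PLY file")
    hd_end <- which(lines == "end_header")
    hd <- lines[seq_len(hd_end)]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hd, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", hd, value = TRUE)))
    v <- do.call(rbind, lapply(lines[hd_end + seq_len(nv)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]][1:3])
    }))
    frows <- lapply(lines[hd_end + nv + seq_len(nf)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]])
    })
  } else {
    stop("unsupported mesh format: ", fmt)
  }
  missing_attr <- FALSE
  faces <- vector("list", length(frows))
  absorber <- integer(length(frows))
  for (i in seq_along(frows)) {
    r <- frows[[i]]
    k <- r[1]
    faces[[i]] <- as.integer(r[1 + seq_len(k)]) + 1L
    if (length(r) >= k + 2) absorber[i] <- as.integer(r[k + 2]) else {
      missing_attr <- TRUE
      absorber[i] <- 0L
    }
  }
  if (missing_attr) {
    warning("face absorber attribute missing: all such faces read as reflecting")
  }
  convex_polyhedron(v, faces, absorber)
}
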
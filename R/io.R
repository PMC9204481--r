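## Pullback serialization. JSON is the canonical schema (schema_version 1,
## shipped as inst/extdata/pullback-schema.json); CSV is a flat one-row-per-
## frame export in which vector fields are packed into delimited strings.

FRAME_FIELDS <- c("frame_index", "z_mm", "lumen_radius", "lumen_area_mm2",
                  "eem_area_mm2", "stent_area_mm2", "neointima_thickness_mm",
                  "arcs", "cap_thickness_um", "rupture_present",
                  "approximated_lumen_radius", "rupture_depth_mm",
                  "thrombus_quadrants", "microchannel_diameter_um",
                  "cholesterol_crystal", "meta")

frame_to_plain <- function(fr) {
  out <- fr[FRAME_FIELDS]
  out$arcs <- lapply(fr$arcs, function(a) {
    list(start_deg = a$start_deg, end_deg = a$end_deg, kind = a$kind)
  })
  out[!vapply(out, is.null, logical(1))]
}

plain_to_frame <- function(x) {
  known <- intersect(names(x), FRAME_FIELDS)
  extra <- setdiff(names(x), FRAME_FIELDS)
  args <- x[setdiff(known, c("arcs", "meta"))]
  # JSON integers parse as integer; all quantitative fields are doubles
  dbl <- c("z_mm", "lumen_area_mm2", "eem_area_mm2", "stent_area_mm2",
           "neointima_thickness_mm", "rupture_depth_mm",
           "microchannel_diameter_um")
  for (f in intersect(names(args), dbl)) args[[f]] <- as.numeric(args[[f]])
  args$arcs <- lapply(x$arcs, function(a) {
    arc_span(a$start_deg, a$end_deg, a$kind)
  })
  meta <- if (!is.null(x$meta)) as.list(x$meta) else list()
  if (length(extra)) meta <- c(meta, x[extra])  # unknown fields preserved
  args$meta <- meta
  num_vec <- c("lumen_radius", "cap_thickness_um", "approximated_lumen_radius")
  for (f in intersect(names(args), num_vec)) {
    args[[f]] <- as.numeric(unlist(args[[f]]))
  }
  args$thrombus_quadrants <- unlist(args$thrombus_quadrants)
  do.call(frame_annotation, args)
}

#' Write a pullback to disk
#'
#' JSON is the canonical, lossless format; CSV is a flat frame table (one row
#' per frame, pullback-level fields in `#key=value` header lines, vector
#' fields packed as `;`-separated strings and arcs as `kind:start:end`
#' triplets joined by `|`).
#'
#' @param pb an `oct_pullback`.
#' @param path output file path.
#' @param format `"json"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_pullback()]
#' @export
write_pullback <- function(pb, path, format = c("json", "csv")) {
  format <- match.arg(format)
  validate_pullback(pb)
  if (format == "json") {
    obj <- list(schema_version = SCHEMA_VERSION, id = pb$id,
                frame_spacing_mm = pb$frame_spacing_mm, group = pb$group,
                vessel = pb$vessel, patient_meta = pb$patient_meta,
                frames = lapply(pb$frames, frame_to_plain))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", pretty = TRUE)
  } else {
    df <- pullback_frame_table(pb)
    hdr <- c(sprintf("#schema_version=%d", SCHEMA_VERSION),
             sprintf("#id=%s", pb$id),
             sprintf("#frame_spacing_mm=%.17g", pb$frame_spacing_mm),
             sprintf("#group=%s", pb$group),
             sprintf("#vessel=%s", pb$vessel))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

pack_num <- function(v) {
  if (is.null(v)) "" else paste(sprintf("%.17g", v), collapse = ";")
}
unpack_num <- function(s) {
  if (is.na(s) || !nzchar(s)) NULL else as.numeric(strsplit(s, ";")[[1]])
}
pack_opt <- function(v) if (is.null(v)) NA_real_ else v

#' Flat frame table of a pullback
#'
#' @param pb an `oct_pullback`.
#' @return A data.frame with one row per frame; the column layout used by the
#'   CSV export.
#' @export
pullback_frame_table <- function(pb) {
  rows <- lapply(pb$frames, function(fr) {
    data.frame(
      frame_index = fr$frame_index, z_mm = fr$z_mm,
      lumen_area_mm2 = pack_opt(fr$lumen_area_mm2),
      eem_area_mm2 = pack_opt(fr$eem_area_mm2),
      stent_area_mm2 = pack_opt(fr$stent_area_mm2),
      neointima_thickness_mm = pack_opt(fr$neointima_thickness_mm),
      rupture_present = fr$rupture_present,
      rupture_depth_mm = pack_opt(fr$rupture_depth_mm),
      microchannel_diameter_um = pack_opt(fr$microchannel_diameter_um),
      cholesterol_crystal = fr$cholesterol_crystal,
      thrombus_q1 = fr$thrombus_quadrants[1],
      thrombus_q2 = fr$thrombus_quadrants[2],
      thrombus_q3 = fr$thrombus_quadrants[3],
      thrombus_q4 = fr$thrombus_quadrants[4],
      arcs = paste(vapply(fr$arcs, function(a) {
        sprintf("%s:%.17g:%.17g", a$kind, a$start_deg, a$end_deg)
      }, character(1)), collapse = "|"),
      lumen_radius = pack_num(fr$lumen_radius),
      cap_thickness_um = pack_num(fr$cap_thickness_um),
      approximated_lumen_radius = pack_num(fr$approximated_lumen_radius),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a pullback from disk
#'
#' Parses and fully validates a pullback written by [write_pullback()] (or by
#' any tool emitting the shipped JSON schema). Unknown frame-level JSON
#' fields are preserved in each frame's `meta` map. Any invariant violation
#' raises an error naming the frame index and field.
#'
#' @param path input file path.
#' @param format `"json"` (default) or `"csv"`.
#' @return A validated `oct_pullback`.
#' @export
read_pullback <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$schema_version) || obj$schema_version != SCHEMA_VERSION) {
      stop("unsupported schema_version: ",
           format(obj$schema_version %||% "missing"))
    }
    frames <- lapply(obj$frames, plain_to_frame)
    pullback(frames, frame_spacing_mm = obj$frame_spacing_mm,
             group = obj$group, vessel = obj$vessel,
             patient_meta = if (is.null(obj$patient_meta)) list() else
               as.list(obj$patient_meta),
             id = obj$id)
  } else {
    lines <- readLines(path)
    hdr_n <- sum(startsWith(lines, "#"))
    kv <- strsplit(sub("^#", "", lines[seq_len(hdr_n)]), "=", fixed = TRUE)
    hdr <- stats::setNames(vapply(kv, `[`, character(1), 2),
                           vapply(kv, `[`, character(1), 1))
    df <- utils::read.csv(textConnection(lines[-seq_len(hdr_n)]),
                          stringsAsFactors = FALSE,
                          colClasses = c(arcs = "character",
                                         lumen_radius = "character",
                                         cap_thickness_um = "character",
                                         approximated_lumen_radius = "character"))
    frames <- lapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      arcs <- list()
      if (nzchar(r$arcs) && !is.na(r$arcs)) {
        arcs <- lapply(strsplit(r$arcs, "|", fixed = TRUE)[[1]], function(s) {
          p <- strsplit(s, ":", fixed = TRUE)[[1]]
          arc_span(as.numeric(p[2]), as.numeric(p[3]), p[1])
        })
      }
      opt <- function(v) if (is.na(v)) NULL else v
      frame_annotation(
        frame_index = r$frame_index, z_mm = r$z_mm,
        lumen_radius = unpack_num(r$lumen_radius),
        lumen_area_mm2 = opt(r$lumen_area_mm2),
        eem_area_mm2 = opt(r$eem_area_mm2),
        stent_area_mm2 = opt(r$stent_area_mm2),
        neointima_thickness_mm = opt(r$neointima_thickness_mm),
        arcs = arcs, cap_thickness_um = unpack_num(r$cap_thickness_um),
        rupture_present = r$rupture_present,
        approximated_lumen_radius = unpack_num(r$approximated_lumen_radius),
        rupture_depth_mm = opt(r$rupture_depth_mm),
        thrombus_quadrants = c(r$thrombus_q1, r$thrombus_q2,
                               r$thrombus_q3, r$thrombus_q4),
        microchannel_diameter_um = opt(r$microchannel_diameter_um),
        cholesterol_crystal = r$cholesterol_crystal)
    })
    pullback(frames, frame_spacing_mm = as.numeric(hdr[["frame_spacing_mm"]]),
             group = hdr[["group"]], vessel = hdr[["vessel"]],
             id = hdr[["id"]])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
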
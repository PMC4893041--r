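# fixture builders shared across the suite; everything is generated in code

# axis-aligned rectangle polygon, vertices (row, col)
rect_roi <- function(top, left, height, width) {
  rbind(c(top, left), c(top, left + width),
        c(top + height, left + width), c(top + height, left))
}

uniform_frame <- function(n = 32, value = 10) {
  planar_frame(matrix(value, n, n))
}

# one joint target + one calf background on an n x n grid
basic_roiset <- function(n = 32) {
  roi_set(list(
    joint = list(vertices = rect_roi(4, 4, 6, 6), role = "joint"),
    calf = list(vertices = rect_roi(n - 12, 4, 8, 8), role = "background_calf")
  ))
}

# noiseless dynamic series from a per-frame gland value function; gland block
# rows 4..11 / cols 4..11, background elsewhere constant
noiseless_series <- function(gland_per_frame, bg_per_frame = 120, n = 24,
                             frame_s = 240, stimulus_s = 960) {
  frames <- lapply(seq_along(gland_per_frame), function(i) {
    m <- matrix(bg_per_frame, n, n)
    m[5:12, 5:12] <- gland_per_frame[i]
    planar_frame(m, acquisition_start_s = (i - 1) * frame_s,
                 duration_s = frame_s)
  })
  dynamic_series(frames, stimulus_time_s = stimulus_s)
}

sgs_roiset <- function(n = 24) {
  roi_set(list(
    parotid = list(vertices = rect_roi(4, 4, 7, 7), role = "gland"),
    temporal = list(vertices = rect_roi(16, 16, 6, 6),
                    role = "background_temporal")
  ))
}

# independent DICOM writing oracle (pydicom); returns list(dcm, pixels_tsv)
write_dicom_oracle <- function(rows = 128, cols = 128, n_frames = 1,
                               frame_ms = 600000, seed = 42) {
  dcm <- tempfile(fileext = ".dcm")
  tsv <- tempfile(fileext = ".tsv")
  script <- sprintf('
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
rng = np.random.default_rng(%d)
nf, rows, cols = %d, %d, %d
arr = rng.integers(0, 500, size=(nf, rows, cols)).astype(np.uint16)
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.20"
meta.MediaStorageSOPInstanceUID = generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = Dataset(); ds.file_meta = meta
ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
ds.Modality = "NM"; ds.SeriesDescription = "hands-anterior"
ds.Rows, ds.Columns = rows, cols
ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
ds.PixelRepresentation = 0; ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.PixelSpacing = ["4.664", "4.664"]
ds.ActualFrameDuration = %d
if nf > 1:
    ds.NumberOfFrames = nf
ds.PixelData = arr.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
np.savetxt(r"%s", arr.reshape(nf * rows, cols), fmt="%%d", delimiter="\\t")
', seed, n_frames, rows, cols, frame_ms, dcm, tsv)
  status <- suppressWarnings(system2("python", "-", input = script,
                                     stdout = FALSE, stderr = FALSE))
  list(dcm = dcm, tsv = tsv, ok = identical(status, 0L))
}
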
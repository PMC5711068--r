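# DICOM fixtures are generated at test time with pydicom (via the python
# interpreter on PATH), which doubles as an independent writer for checking
# this package's reader.

make_rtplan_fixture <- function(path) {
  script <- sprintf('
import pydicom
from pydicom.dataset import Dataset, FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.481.5"
meta.MediaStorageSOPInstanceUID = generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = FileDataset(r"%s", {}, file_meta=meta, preamble=b"\\x00" * 128)
ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.Modality = "RTPLAN"
ds.PatientID = "FIX01"

def cp(index, cum, mlc=None, gantry=None):
    c = Dataset()
    c.ControlPointIndex = index
    c.CumulativeMetersetWeight = cum
    if gantry is not None:
        c.GantryAngle = gantry
    if mlc is not None:
        b = Dataset()
        b.RTBeamLimitingDeviceType = "MLCX"
        b.LeafJawPositions = mlc
        c.BeamLimitingDevicePositionSequence = [b]
    return c

# beam 1: static, one segment (2 control points, same MLC)
b1 = Dataset()
b1.BeamNumber = 1
b1.FinalCumulativeMetersetWeight = 1.0
mlc1 = [-30.0, -20.0, -10.0, 10.0, 20.0, 30.0]   # 3 pairs, mm
b1.ControlPointSequence = [cp(0, 0.0, mlc1, gantry=40.0), cp(1, 1.0, mlc1)]

# beam 2: dynamic, 3 control points -> 2 segments with meterset 0.25/0.75
b2 = Dataset()
b2.BeamNumber = 2
b2.FinalCumulativeMetersetWeight = 1.0
mlc2a = [-40.0, -40.0, -40.0, 0.0, 0.0, 0.0]
mlc2b = [-20.0, -20.0, -20.0, 20.0, 20.0, 20.0]
mlc2c = [0.0, 0.0, 0.0, 40.0, 40.0, 40.0]
b2.ControlPointSequence = [cp(0, 0.0, mlc2a, gantry=180.0),
                           cp(1, 0.25, mlc2b), cp(2, 1.0, mlc2c)]

ds.BeamSequence = [b1, b2]
fg = Dataset()
rb1 = Dataset(); rb1.ReferencedBeamNumber = 1; rb1.BeamMeterset = 120.0
rb2 = Dataset(); rb2.ReferencedBeamNumber = 2; rb2.BeamMeterset = 80.0
fg.ReferencedBeamSequence = [rb1, rb2]
ds.FractionGroupSequence = [fg]
ds.save_as(r"%s", enforce_file_format=True)
', path, path)
  run_python(script)
}

make_rtdose_fixture <- function(path) {
  script <- sprintf('
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.481.2"
meta.MediaStorageSOPInstanceUID = generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = FileDataset(r"%s", {}, file_meta=meta, preamble=b"\\x00" * 128)
ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.Modality = "RTDOSE"
ds.Rows = 4
ds.Columns = 5
ds.NumberOfFrames = 3
ds.PixelSpacing = [2.0, 3.0]          # row, col in mm
ds.GridFrameOffsetVector = [0.0, 4.0, 8.0]
ds.ImagePositionPatient = [-6.0, -3.0, -4.0]
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.BitsAllocated = 32
ds.BitsStored = 32
ds.HighBit = 31
ds.PixelRepresentation = 0
ds.DoseUnits = "GY"
ds.DoseGridScaling = 1e-3
arr = np.arange(60, dtype=np.uint32).reshape(3, 4, 5)  # frame, row, col
ds.PixelData = arr.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
np.save(r"%s.npy", arr)
', path, path, path)
  run_python(script)
}

run_python <- function(script) {
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  out <- suppressWarnings(
    system2("python", f, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python fixture generation failed: ",
         paste(out, collapse = "\n"))
  invisible(TRUE)
}
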
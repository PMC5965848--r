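"""Write a synthetic DICOM series for reader tests.

Usage: python make_dicom.py config.json

config: {"dir": str, "nx": int, "ny": int, "nz": int,
         "spacing": [dx, dy, dz], "values": [flat, x fastest],
         "filenames": [per-slice name], "series_uids": [per-slice UID],
         "z_positions": [per-slice z, mm]}
Values must be integers in [0, 65535]; stored verbatim as uint16.
"""
import json
import sys

import numpy as np
import pydicom
from pydicom.dataset import FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

cfg = json.load(open(sys.argv[1]))
nx, ny, nz = cfg["nx"], cfg["ny"], cfg["nz"]
vol = np.asarray(cfg["values"], dtype=np.uint16).reshape(nz, ny, nx)
dx, dy, dz = cfg["spacing"]

for k in range(nz):
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = pydicom.uid.UID(
        "1.2.840.10008.5.1.4.1.1.128")  # PET image storage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = FileDataset(None, {}, file_meta=meta, preamble=b"\0" * 128)
    ds.SOPClassUID = meta.MediaStorageSOPClassUID
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = cfg["series_uids"][k]
    ds.Modality = "PT"
    ds.Rows = ny
    ds.Columns = nx
    ds.PixelSpacing = [str(dy), str(dx)]  # (between rows, between cols)
    ds.ImagePositionPatient = ["0", "0", str(cfg["z_positions"][k])]
    ds.ImageOrientationPatient = ["1", "0", "0", "0", "1", "0"]
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.RescaleSlope = "1"
    ds.RescaleIntercept = "0"
    ds.PixelData = vol[k].tobytes()
    ds.save_as(f"{cfg['dir']}/{cfg['filenames'][k]}",
               enforce_file_format=True)
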
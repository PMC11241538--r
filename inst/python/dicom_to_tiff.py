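"""Convert a (multi-frame) DICOM file to the package's TIFF + JSON format.

Usage: python dicom_to_tiff.py <in.dcm> <out.tif>

Frame times come from FrameTimeVector / FrameTime (ms) when present, else
from CineRate / RecommendedDisplayFrameRate, else 30 fps. Calibration comes
from PixelSpacing or ImagerPixelSpacing (mm) when present.
"""
import json
import sys

import numpy as np
import pydicom
import tifffile


def main(src, dst):
    ds = pydicom.dcmread(src)
    px = ds.pixel_array
    if px.ndim == 2:
        px = px[None, :, :]
    if px.ndim != 3:
        raise SystemExit("only grayscale multi-frame DICOM is supported")
    px = np.ascontiguousarray(px).astype(np.uint16)

    n = px.shape[0]
    rate = float(getattr(ds, "CineRate", 0) or
                 getattr(ds, "RecommendedDisplayFrameRate", 0) or 30.0)
    ftv = getattr(ds, "FrameTimeVector", None)
    if ftv is not None and len(ftv) == n:
        times = np.cumsum([0.0] + [float(v) / 1000.0 for v in ftv[1:]])
    else:
        ft = getattr(ds, "FrameTime", None)
        dt = float(ft) / 1000.0 if ft else 1.0 / rate
        times = np.arange(n) * dt
        rate = 1.0 / dt

    spacing = (getattr(ds, "PixelSpacing", None) or
               getattr(ds, "ImagerPixelSpacing", None))
    meta = {"times": [float(t) for t in times], "frame_rate": rate}
    if spacing is not None:
        meta["mm_per_px"] = float(spacing[0])

    tifffile.imwrite(dst, px, photometric="minisblack")
    with open(dst + ".json", "w") as fh:
        json.dump(meta, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
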
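"""Keypoint/descriptor extraction worker.

Reads a JSON job description, runs the requested scikit-image detector
(ORB or SIFT) on each listed image restricted to an optional binary
mask, and writes:

  result.json  per-image keypoint counts / error strings, descriptor dim
  kp.bin       float64 little-endian (n_total x 5) row-major:
               row, col, scale, orientation_deg, response
  desc.bin     uint8 (n_total x d) row-major descriptors
               (ORB: 256 bits packed to 32 bytes; SIFT: 128 bytes)

Images arrive as headerless column-major uint8 dumps ({path, h, w}),
which avoids PNG codec overhead on the hot path. Everything here is
deterministic: scikit-image's ORB and SIFT have no stochastic component.
"""
import json
import sys

import numpy as np
from skimage.feature import ORB, SIFT


def load_u8(entry):
    data = np.fromfile(entry["path"], dtype=np.uint8)
    h, w = int(entry["h"]), int(entry["w"])
    if data.size != h * w:
        raise ValueError(f"{entry['path']}: expected {h * w} bytes, "
                         f"got {data.size}")
    return data.reshape((h, w), order="F")


def detect(method, img, max_keypoints, params):
    if method == "ORB":
        det = ORB(n_keypoints=int(max_keypoints),
                  downscale=float(params.get("downscale", 1.2)),
                  n_scales=int(params.get("n_scales", 8)),
                  fast_threshold=float(params.get("fast_threshold", 0.08)))
        det.detect_and_extract(img)
        desc = np.packbits(det.descriptors.astype(bool), axis=1)  # 256 bits -> 32 bytes
        resp = det.responses.astype(np.float64)
        scales = det.scales.astype(np.float64)
        ori = det.orientations.astype(np.float64)
        kp = det.keypoints.astype(np.float64)
    elif method == "SIFT":
        det = SIFT()
        det.detect_and_extract(img)
        desc = det.descriptors.astype(np.uint8)
        resp = np.zeros(len(det.keypoints))  # SIFT exposes no response score
        scales = det.sigmas.astype(np.float64)
        ori = det.orientations.astype(np.float64)
        kp = det.keypoints.astype(np.float64)
    else:
        raise ValueError(f"unknown method {method}")
    ori_deg = np.degrees(ori) % 360.0
    return kp, scales, ori_deg, resp, desc


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    method = job["method"]
    max_kp = int(job["max_keypoints"])
    params = job.get("detector_params") or {}

    mask = None
    crop = None
    r0 = c0 = 0
    if job.get("mask"):
        mask = load_u8(job["mask"]) > 0
        rows = np.flatnonzero(mask.any(axis=1))
        cols = np.flatnonzero(mask.any(axis=0))
        if rows.size and cols.size:
            r0, c0 = rows[0], cols[0]
            crop = (slice(rows[0], rows[-1] + 1), slice(cols[0], cols[-1] + 1))

    entries = []
    kp_rows = []
    desc_rows = []
    d = {"ORB": 32, "SIFT": 128}[method]
    for entry in job["images"]:
        out_entry = {"n": 0, "error": None}
        try:
            img = load_u8(entry).astype(np.float64) / 255.0
            if mask is not None and crop is None:  # all-false mask
                entries.append(out_entry)
                continue
            sub = img if mask is None else img[crop]
            try:
                kp, scales, ori, resp, desc = detect(method, sub, max_kp, params)
            except RuntimeError:
                entries.append(out_entry)  # detector found no features
                continue
            kp = kp + np.array([r0, c0], dtype=np.float64)
            if mask is not None:
                ri = np.clip(np.rint(kp[:, 0]).astype(int), 0, mask.shape[0] - 1)
                ci = np.clip(np.rint(kp[:, 1]).astype(int), 0, mask.shape[1] - 1)
                keep = mask[ri, ci]
                kp, scales, ori, resp, desc = (
                    kp[keep], scales[keep], ori[keep], resp[keep], desc[keep])
            order = np.argsort(-resp, kind="stable")[:max_kp]
            kp, scales, ori, resp, desc = (
                kp[order], scales[order], ori[order], resp[order], desc[order])
            out_entry["n"] = int(len(kp))
            if len(kp):
                kp_rows.append(np.column_stack([kp, scales, ori, resp]))
                desc_rows.append(desc)
        except Exception as exc:  # unreadable image etc.; isolate per image
            out_entry["error"] = str(exc)
        entries.append(out_entry)

    out = job["out_dir"]
    kp_all = (np.vstack(kp_rows) if kp_rows
              else np.zeros((0, 5), dtype=np.float64))
    desc_all = (np.vstack(desc_rows) if desc_rows
                else np.zeros((0, d), dtype=np.uint8))
    with open(f"{out}/kp.bin", "wb") as fh:
        fh.write(np.ascontiguousarray(kp_all, dtype="<f8").tobytes())
    with open(f"{out}/desc.bin", "wb") as fh:
        fh.write(np.ascontiguousarray(desc_all, dtype=np.uint8).tobytes())
    with open(f"{out}/result.json", "w") as fh:
        json.dump({"images": entries, "d": d, "method": method}, fh)


if __name__ == "__main__":
    main(sys.argv[1])
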
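#!/usr/bin/env python
"""Minimal HDF5 <-> exchange-directory bridge.

Used by the R converter functions; all structural conversion decisions live on
the R side.  The exchange directory holds a manifest.json plus one .npy file
per dataset payload.

  dump  <file.h5> <exchange_dir>   HDF5 -> manifest + npy payloads
  build <exchange_dir> <file.h5>   manifest + npy payloads -> HDF5

Attribute values are typed in the manifest ({"key":k,"t":tag,"v":value}) so
integer/float/bool/string kinds survive the JSON hop in both directions.
Non-finite floats travel as the strings "nan"/"inf"/"-inf".
"""

import json
import os
import sys

import h5py
import numpy as np

FLOAT_SPECIAL = {"nan": float("nan"), "inf": float("inf"), "-inf": float("-inf")}


def enc_float(x):
    x = float(x)
    if np.isnan(x):
        return "nan"
    if np.isinf(x):
        return "inf" if x > 0 else "-inf"
    return x


def dec_float(x):
    if isinstance(x, str):
        return FLOAT_SPECIAL.get(x, None) if x in FLOAT_SPECIAL else float(x)
    return float(x)


def encode_attr(key, value, lossy, path):
    if isinstance(value, bytes):
        lossy.append({"path": path, "description":
                      "byte-string attribute '%s' decoded as UTF-8" % key})
        return {"key": key, "t": "s", "v": value.decode("utf-8", "surrogateescape")}
    if isinstance(value, str):
        return {"key": key, "t": "s", "v": value}
    if isinstance(value, (bool, np.bool_)):
        return {"key": key, "t": "b", "v": bool(value)}
    if isinstance(value, (int, np.integer)):
        return {"key": key, "t": "i", "v": int(value)}
    if isinstance(value, (float, np.floating)):
        return {"key": key, "t": "f", "v": enc_float(value)}
    if isinstance(value, np.ndarray):
        if value.ndim != 1:
            return None
        k = value.dtype.kind
        if k in "iu":
            return {"key": key, "t": "ia", "v": [int(v) for v in value]}
        if k == "f":
            return {"key": key, "t": "fa", "v": [enc_float(v) for v in value]}
        if k == "b":
            return {"key": key, "t": "ba", "v": [bool(v) for v in value]}
        if k in "SU" or k == "O":
            out = []
            for v in value:
                if isinstance(v, bytes):
                    v = v.decode("utf-8", "surrogateescape")
                if not isinstance(v, str):
                    return None
                out.append(v)
            return {"key": key, "t": "sa", "v": out}
    return None


def decode_attr(entry):
    t, v = entry["t"], entry["v"]
    if t == "i":
        return np.int64(v)
    if t == "f":
        return np.float64(dec_float(v))
    if t == "b":
        return np.bool_(v)
    if t == "s":
        return v
    if t == "ia":
        return np.asarray(v, dtype=np.int64)
    if t == "fa":
        return np.asarray([dec_float(x) for x in v], dtype=np.float64)
    if t == "ba":
        return np.asarray(v, dtype=bool)
    if t == "sa":
        return [str(x) for x in v]
    raise ValueError("unknown attr tag %r" % t)


def dump(h5path, exch):
    os.makedirs(exch, exist_ok=True)
    objects, skipped, lossy = [], [], []
    counter = [0]

    def attrs_of(node, path):
        out = []
        for key in node.attrs:
            try:
                value = node.attrs[key]
            except (OSError, TypeError):
                skipped.append({"path": path, "reason":
                                "unreadable attribute '%s'" % key})
                continue
            enc = encode_attr(key, value, lossy, path)
            if enc is None:
                skipped.append({"path": path, "reason":
                                "attribute '%s' has no Exdir counterpart" % key})
            else:
                out.append(enc)
        return out

    def visit(name, parent):
        for key in parent.keys():
            path = name + key if not name else name + "/" + key
            link = parent.get(key, getlink=True)
            if isinstance(link, (h5py.SoftLink, h5py.ExternalLink)):
                skipped.append({"path": path, "reason": "links unsupported"})
                continue
            node = parent[key]
            if isinstance(node, h5py.Group):
                objects.append({"path": path, "kind": "group",
                                "attrs": attrs_of(node, path)})
                visit(path, node)
            elif isinstance(node, h5py.Dataset):
                dt = node.dtype
                if dt.kind not in "iufbSU":
                    skipped.append({"path": path, "reason":
                                    "dataset dtype '%s' has no Exdir counterpart" % dt})
                    continue
                fn = "d%05d.npy" % counter[0]
                counter[0] += 1
                np.save(os.path.join(exch, fn), node[()] if node.shape == () else node[...])
                objects.append({"path": path, "kind": "dataset", "npy": fn,
                                "shape": list(node.shape),
                                "attrs": attrs_of(node, path)})
            else:
                skipped.append({"path": path, "reason":
                                "object class %s unsupported" % type(node).__name__})

    with h5py.File(h5path, "r") as f:
        root_attrs = attrs_of(f, "/")
        visit("", f)

    manifest = {"root_attrs": root_attrs, "objects": objects,
                "skipped": skipped, "lossy": lossy}
    with open(os.path.join(exch, "manifest.json"), "w") as fh:
        json.dump(manifest, fh)


def build(exch, h5path):
    with open(os.path.join(exch, "manifest.json")) as fh:
        manifest = json.load(fh)
    with h5py.File(h5path, "w") as f:
        for entry in manifest.get("root_attrs", []):
            f.attrs[entry["key"]] = decode_attr(entry)
        for obj in manifest["objects"]:
            if obj["kind"] == "group":
                node = f.create_group(obj["path"])
            else:
                npy = obj["npy"]
                if not os.path.isabs(npy):
                    npy = os.path.join(exch, npy)
                arr = np.load(npy)
                node = f.create_dataset(obj["path"], data=arr)
            for entry in obj.get("attrs", []):
                node.attrs[entry["key"]] = decode_attr(entry)


def main(argv):
    if len(argv) != 3 or argv[0] not in ("dump", "build"):
        sys.stderr.write(__doc__)
        return 2
    if argv[0] == "dump":
        dump(argv[1], argv[2])
    else:
        build(argv[1], argv[2])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
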
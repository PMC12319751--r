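"""Convert between the micica fixture container and Neuromag FIF.

Usage:
    python fif_bridge.py to-fif   <fixture_dir> <out.fif>
    python fif_bridge.py from-fif <in.fif>      <fixture_dir>

Event stim codes: G1..G10 -> 1..10, picture onsets -> 21 (vocal),
22 (silent), 23 (observation). Durations are restored from the task on
read-back (gesture 3.2 s, vocal/silent 4.0 s, observation 2.0 s).
"""
import json
import os
import sys

import numpy as np
import pyarrow.feather as feather
import pyarrow as pa

LABEL_CODES = {f"G{i}": i for i in range(1, 11)}
PICTURE_CODES = {"vocal": 21, "silent": 22, "observation": 23}
CODE_TASKS = {i: "gesture" for i in range(1, 11)}
CODE_TASKS.update({21: "vocal", 22: "silent", 23: "observation"})
TASK_DURATIONS = {"gesture": 3.2, "vocal": 4.0, "silent": 4.0,
                  "observation": 2.0}
STIM_NAME = "STI101"


def event_code(label, task):
    if label == "picture":
        return PICTURE_CODES[task]
    return LABEL_CODES[label]


def to_fif(fixture_dir, out_path):
    import mne

    with open(os.path.join(fixture_dir, "meta.json")) as fh:
        meta = json.load(fh)
    channels = feather.read_table(
        os.path.join(fixture_dir, "channels.feather")).to_pandas()
    data = feather.read_table(
        os.path.join(fixture_dir, "data.feather")).to_pandas().to_numpy().T
    events = feather.read_table(
        os.path.join(fixture_dir, "events.feather")).to_pandas()

    names = list(channels["name"]) + [STIM_NAME]
    types = list(channels["kind"]) + ["stim"]
    stim = np.zeros(data.shape[1])
    for _, ev in events.iterrows():
        onset = int(ev["onset_sample"])
        stim[onset:onset + 3] = event_code(ev["label"], ev["task"])
    full = np.vstack([data, stim[None, :]])

    info = mne.create_info(names, float(meta["sfreq"]), ch_types=types,
                           verbose="error")
    raw = mne.io.RawArray(full, info, verbose="error")
    raw.save(out_path, fmt="double", overwrite=True, verbose="error")


def from_fif(in_path, fixture_dir):
    import mne

    raw = mne.io.read_raw_fif(in_path, preload=True, verbose="error")
    picks = [i for i, ch in enumerate(raw.info["chs"])
             if raw.info.get_channel_types()[i] != "stim"]
    kinds = [raw.info.get_channel_types()[i] for i in picks]
    names = [raw.ch_names[i] for i in picks]
    data = raw.get_data()[picks, :]

    # Neuromag pair ids: planar gradiometers of one sensor element share the
    # name prefix, differing only in the final digit (…2 / …3).
    pair_id, pairs = [], {}
    for name, kind in zip(names, kinds):
        if kind == "grad":
            key = name.strip()[:-1]
            pair_id.append(pairs.setdefault(key, len(pairs) + 1))
        else:
            pair_id.append(None)

    pos = [(ch["loc"][0], ch["loc"][1]) for ch in
           [raw.info["chs"][i] for i in picks]]
    channels = pa.table({
        "name": names, "kind": kinds,
        "pair_id": pa.array(pair_id, type=pa.int32()),
        "pos_x": [p[0] if any(p) else None for p in pos],
        "pos_y": [p[1] if any(p) else None for p in pos],
    })

    stim_idx = [i for i, t in enumerate(raw.info.get_channel_types())
                if t == "stim"]
    onsets, labels, tasks, durs = [], [], [], []
    if stim_idx:
        try:
            ev = mne.find_events(raw, stim_channel=raw.ch_names[stim_idx[0]],
                                 verbose="error")
        except ValueError:
            ev = np.zeros((0, 3), dtype=int)
        for onset, _, code in ev:
            task = CODE_TASKS.get(int(code))
            if task is None:
                continue
            onsets.append(int(onset) - raw.first_samp)
            labels.append("picture" if int(code) >= 21 else f"G{int(code)}")
            tasks.append(task)
            durs.append(TASK_DURATIONS[task])
    events = pa.table({
        "onset_sample": pa.array(onsets, type=pa.int32()),
        "label": pa.array(labels, type=pa.string()),
        "task": pa.array(tasks, type=pa.string()),
        "run": pa.array([1] * len(onsets), type=pa.int32()),
        "block": pa.array([1] * len(onsets), type=pa.int32()),
        "duration_s": pa.array(durs, type=pa.float64()),
    })

    os.makedirs(fixture_dir, exist_ok=True)
    with open(os.path.join(fixture_dir, "meta.json"), "w") as fh:
        json.dump({"format_version": 1, "sfreq": raw.info["sfreq"],
                   "first_sample_time": raw.first_samp / raw.info["sfreq"],
                   "run_starts": [0]}, fh)
    feather.write_feather(channels,
                          os.path.join(fixture_dir, "channels.feather"))
    cols = {name: data[i, :] for i, name in enumerate(names)}
    feather.write_feather(pa.table(cols),
                          os.path.join(fixture_dir, "data.feather"))
    feather.write_feather(events,
                          os.path.join(fixture_dir, "events.feather"))


def main():
    if len(sys.argv) != 4 or sys.argv[1] not in ("to-fif", "from-fif"):
        sys.exit(__doc__)
    if sys.argv[1] == "to-fif":
        to_fif(sys.argv[2], sys.argv[3])
    else:
        from_fif(sys.argv[2], sys.argv[3])


if __name__ == "__main__":
    main()
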
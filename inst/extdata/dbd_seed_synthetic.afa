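>dbd_seed_1 synthetic plant Hsf DBD seed consensus
LPKFLAKTYEMVEDPATDAIVSWSGNSFVVWDPELAREVLPKYFKHNNFSSFVRQLNTYGFRKVDPDRWEFANEDFLRGQKHLLKNI
>dbd_seed_2 synthetic variant
LPKFLAKTYEMVEDPATYAIVSWSCNSFVVWDPELAREVLPKYFKHDNQSSFVRQLNTYGFRKVCPDRWEFANPDFLRGQKHLLKNS
>dbd_seed_3 synthetic variant
LPDFSAKTYEMVEDPATDAIVSWSGNIFVVWDPHLKREVLAKYFKHNNFSSFVRQLNDYGFRKVDPDRWEFANEDFLRGQKHLLKNI
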
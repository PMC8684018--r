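race,sex,factor,not_meeting_pct
all,men,red_meat,59.9
all,men,processed_meat,88.1
all,men,fiber,88
all,men,calcium,53.4
all,women,red_meat,45.4
all,women,processed_meat,83.9
all,women,fiber,95.6
all,women,calcium,71.7
all,persons,red_meat,52.7
all,persons,processed_meat,86
all,persons,fiber,92
all,persons,calcium,63
nh_white,men,red_meat,63.9
nh_white,men,processed_meat,91.6
nh_white,men,fiber,87.8
nh_white,men,calcium,49.5
nh_white,women,red_meat,48.7
nh_white,women,processed_meat,85.9
nh_white,women,fiber,95.6
nh_white,women,calcium,69.3
nh_white,persons,red_meat,56.4
nh_white,persons,processed_meat,88.8
nh_white,persons,fiber,91.9
nh_white,persons,calcium,59.9
nh_black,men,red_meat,49
nh_black,men,processed_meat,86.6
nh_black,men,fiber,96.4
nh_black,men,calcium,67.4
nh_black,women,red_meat,37.6
nh_black,women,processed_meat,86.7
nh_black,women,fiber,98.3
nh_black,women,calcium,86.6
nh_black,persons,red_meat,42.9
nh_black,persons,processed_meat,86.6
nh_black,persons,fiber,97.5
nh_black,persons,calcium,78.2
hispanic,men,red_meat,52.8
hispanic,men,processed_meat,84.9
hispanic,men,fiber,79.9
hispanic,men,calcium,63.6
hispanic,women,red_meat,40.8
hispanic,women,processed_meat,79.8
hispanic,women,fiber,92.9
hispanic,women,calcium,69
hispanic,persons,red_meat,47.3
hispanic,persons,processed_meat,82.5
hispanic,persons,fiber,86.6
hispanic,persons,calcium,66.4
other,men,red_meat,53.8
other,men,processed_meat,62.5
other,men,fiber,89.3
other,men,calcium,57.2
other,women,red_meat,36.6
other,women,processed_meat,67.9
other,women,fiber,94
other,women,calcium,74.6
other,persons,red_meat,44.9
other,persons,processed_meat,65.3
other,persons,fiber,91.7
other,persons,calcium,66.2
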
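# tweetformer emoji short-name table v1 (codepoint-hex <TAB> short_name)
1F600	grinning_face
1F601	beaming_face_with_smiling_eyes
1F602	face_with_tears_of_joy
1F603	grinning_face_with_big_eyes
1F604	grinning_face_with_smiling_eyes
1F605	grinning_face_with_sweat
1F606	grinning_squinting_face
1F607	smiling_face_with_halo
1F609	winking_face
1F60A	smiling_face_with_smiling_eyes
1F60B	face_savoring_food
1F60D	smiling_face_with_heart_eyes
1F60E	smiling_face_with_sunglasses
1F60F	smirking_face
1F610	neutral_face
1F611	expressionless_face
1F612	unamused_face
1F613	downcast_face_with_sweat
1F614	pensive_face
1F615	confused_face
1F616	confounded_face
1F618	face_blowing_a_kiss
1F61A	kissing_face_with_closed_eyes
1F61C	winking_face_with_tongue
1F61D	squinting_face_with_tongue
1F61E	disappointed_face
1F61F	worried_face
1F620	angry_face
1F621	pouting_face
1F622	crying_face
1F623	persevering_face
1F624	face_with_steam_from_nose
1F625	sad_but_relieved_face
1F628	fearful_face
1F629	weary_face
1F62A	sleepy_face
1F62B	tired_face
1F62C	grimacing_face
1F62D	loudly_crying_face
1F62E	face_with_open_mouth
1F630	anxious_face_with_sweat
1F631	face_screaming_in_fear
1F632	astonished_face
1F633	flushed_face
1F634	sleeping_face
1F635	face_with_crossed_out_eyes
1F637	face_with_medical_mask
1F641	slightly_frowning_face
1F642	slightly_smiling_face
1F643	upside_down_face
1F644	face_with_rolling_eyes
1F910	zipper_mouth_face
1F912	face_with_thermometer
1F913	nerd_face
1F914	thinking_face
1F915	face_with_head_bandage
1F917	hugging_face
1F922	nauseated_face
1F924	drooling_face
1F925	lying_face
1F927	sneezing_face
1F928	face_with_raised_eyebrow
1F92E	face_vomiting
1F970	smiling_face_with_hearts
1F971	yawning_face
1F972	smiling_face_with_tear
1F974	woozy_face
1F975	hot_face
1F976	cold_face
1F97A	pleading_face
2639	frowning_face
263A	smiling_face
1F48A	pill
1F489	syringe
1FA79	adhesive_bandage
1FA7A	stethoscope
1FA78	drop_of_blood
1F9A0	microbe
1F9EA	test_tube
1F9EB	petri_dish
1F9EC	dna
1F321	thermometer
1F691	ambulance
1F3E5	hospital
1F468	man
1F469	woman
1F476	baby
1F9D1	person
1F464	bust_in_silhouette
1F44D	thumbs_up
1F44E	thumbs_down
1F44F	clapping_hands
1F44C	ok_hand
1F44B	waving_hand
1F446	backhand_index_pointing_up
1F447	backhand_index_pointing_down
1F448	backhand_index_pointing_left
1F449	backhand_index_pointing_right
1F450	open_hands
1F64F	folded_hands
1F64C	raising_hands
1F91D	handshake
1F91E	crossed_fingers
1F4AA	flexed_biceps
270A	raised_fist
270B	raised_hand
270C	victory_hand
261D	index_pointing_up
2764	red_heart
1F493	beating_heart
1F494	broken_heart
1F495	two_hearts
1F496	sparkling_heart
1F497	growing_heart
1F499	blue_heart
1F49A	green_heart
1F49B	yellow_heart
1F49C	purple_heart
1F49E	revolving_hearts
1F5A4	black_heart
1F90D	white_heart
1F9E1	orange_heart
1F525	fire
2B50	star
1F31F	glowing_star
2728	sparkles
1F389	party_popper
1F38A	confetti_ball
1F480	skull
1F4A4	zzz
1F4A5	collision
1F4A6	sweat_droplets
1F4A7	droplet
1F4A8	dashing_away
1F4A9	pile_of_poo
1F4AB	dizzy
1F4AF	hundred_points
1F4AD	thought_balloon
1F4AC	speech_balloon
1F648	see_no_evil_monkey
1F649	hear_no_evil_monkey
1F64A	speak_no_evil_monkey
1F436	dog_face
1F431	cat_face
1F984	unicorn
1F37A	beer_mug
1F377	wine_glass
2615	hot_beverage
1F355	pizza
1F354	hamburger
1F34E	red_apple
1F34C	banana
1F966	broccoli
1F6CF	bed
1F6BD	toilet
1F6BF	shower
1F3C3	person_running
1F6B6	person_walking
1F3CB	person_lifting_weights
26A0	warning
26D4	no_entry
2705	check_mark_button
274C	cross_mark
2753	question_mark
2757	exclamation_mark
1F4C8	chart_increasing
1F4C9	chart_decreasing
1F4C5	calendar
1F4F1	mobile_phone
1F4BB	laptop
1F697	automobile
2600	sun
2601	cloud
26C8	cloud_with_lightning_and_rain
2744	snowflake
1F319	crescent_moon
1F308	rainbow
1F332	evergreen_tree
1F33B	sunflower
1F339	rose
1F340	four_leaf_clover
1F343	leaf_fluttering_in_wind
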